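# Shared fixtures, built once per test run and cached.

`%||%` <- function(a, b) if (is.null(a)) b else a

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# compact phantom grid for unit tests (full geometry, fewer slices)
small_phantom_spec <- function(...) {
  phantom_spec(volume_shape = c(96L, 96L, 40L), ...)
}

test_phantom <- function(key = "default", ...) {
  cached(paste0("phantom_", key), generate_phantom(small_phantom_spec(...)))
}

test_detector <- function() cached("detector", default_detector())

# detection -> seeds -> septum on a cached phantom
test_case_stages <- function(key = "default", ...) {
  cached(paste0("stages_", key), {
    ph <- test_phantom(key, ...)
    det <- filter_by_anatomy_prior(detect_slices(ph$volume, test_detector()),
                                   ph$volume)
    sel <- cluster_and_select(det, ph$volume)
    rv_seeds <- seeds_from_cluster(sel$RV, ph$volume)
    lv_seeds <- seeds_from_cluster(sel$LV, ph$volume)
    septum <- estimate_septum(ph$volume, rv_seeds, lv_seeds)
    list(ph = ph, det = det, sel = sel, rv_seeds = rv_seeds,
         lv_seeds = lv_seeds, septum = septum)
  })
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

angle_between_deg <- function(a, b) {
  acos(min(abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)), 1)) * 180 / pi
}

# minimal synthetic caliper for report tests
make_caliper <- function(slice, p1, p2) {
  structure(list(slice_index = slice,
                 endpoints = rbind(p1, p2),
                 length_mm = sqrt(sum((p2 - p1)^2))),
            class = "caliper")
}
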