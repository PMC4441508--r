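# Training fixtures for the window classifiers, built from phantoms.
#
# The published detector this stage replaces was trained on a labelled
# CTPA corpus that is not distributable; the package instead trains its
# linear window models on phantom slices with known chamber boxes. The
# detector interface is pluggable, so a model trained on real labelled
# data can be dropped in via save_detector()/load_detector().

detector_training_specs <- function() {
  ratios <- c(0.75, 0.95, 1.1, 1.3, 1.5, 1.75)
  angles <- c(0, 10, 20, 30, 40, 45)
  noises <- c(0, 5, 10, 15, 20, 10)
  lapply(seq_along(ratios), function(i) {
    phantom_spec(
      rv_semi_axes = c(22 * ratios[i], 22, 32),
      lv_semi_axes = c(22, 21, 32),
      septum_normal_angle = angles[i],
      noise_sigma = noises[i],
      rng_seed = 31000L + i
    )
  })
}

mask_slice_box_mm <- function(mask, k, spacing) {
  ij <- which(mask[, , k], arr.ind = TRUE)
  if (!nrow(ij)) return(NULL)
  c((min(ij[, 1]) - 1) * spacing[1], (min(ij[, 2]) - 1) * spacing[2],
    max(ij[, 1]) * spacing[1], max(ij[, 2]) * spacing[2])
}

#' Labelled training slices from a set of phantoms
#'
#' Extracts mid-ventricular axial slices with their true chamber boxes
#' (positives) and infra-apical slices without any ventricle (negatives).
#'
#' @param specs list of [phantom_spec()]; defaults to the built-in
#'   training set, which is disjoint from the frozen evaluation suite.
#' @return `list(fixtures =, negatives =)` in the format expected by
#'   [train_detector()].
#' @export
detector_training_fixtures <- function(specs = detector_training_specs()) {
  fixtures <- list(); negatives <- list()
  for (spec in specs) {
    ph <- generate_phantom(spec)
    vol <- ph$volume
    sp <- vol$spacing
    kc <- round(mean(ph$truth$rv_slices))
    for (k in kc + c(-6L, -3L, 0L, 3L, 6L)) {
      if (k < 1 || k > dim(vol$voxels)[3]) next
      rb <- mask_slice_box_mm(ph$truth$rv_mask, k, sp)
      lb <- mask_slice_box_mm(ph$truth$lv_mask, k, sp)
      if (is.null(rb) || is.null(lb)) next
      fixtures[[length(fixtures) + 1L]] <-
        list(image = vol$voxels[, , k], spacing = sp[1:2],
             rv_box = rb, lv_box = lb)
    }
    for (k in c(2L, 4L))
      negatives[[length(negatives) + 1L]] <-
        list(image = vol$voxels[, , k], spacing = sp[1:2])
  }
  list(fixtures = fixtures, negatives = negatives)
}

.rvlv_cache <- new.env(parent = emptyenv())

#' Default detector model
#'
#' Trains (once per session, then cached) the per-chamber window models on
#' the built-in phantom training set.
#'
#' @param seed training seed.
#' @param config a [detector_config()].
#' @return a `detector_model`.
#' @export
default_detector <- function(seed = 101L, config = detector_config()) {
  key <- paste0("detector_", seed, "_", config$window_mm, "_", config$grid_n)
  if (!is.null(.rvlv_cache[[key]])) return(.rvlv_cache[[key]])
  td <- detector_training_fixtures()
  model <- train_detector(td$fixtures, td$negatives, config = config, seed = seed)
  .rvlv_cache[[key]] <- model
  model
}
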