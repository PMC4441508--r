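# Caliper positioning and RV/LV ratio estimation.
#
# Each axial slice of a chamber mask yields one caliper: the longest chord
# of the mask along the in-plane projection of the septum normal (i.e.
# perpendicular to the septum trace seen on that slice), measured with
# sub-voxel precision. Because the segmentations can run through the
# atrioventricular valve into the atria, the per-slice contour shape and
# the craniocaudal caliper trend are analysed to find the valve, and only
# calipers between the valve and the apex compete for the maximum. The
# ratio is the RV maximum over the LV maximum; the two maxima may sit on
# different slices.

in_plane_direction <- function(septum) {
  d <- septum$normal[1:2]
  nd <- sqrt(sum(d^2))
  if (nd < 1e-9)
    stop("septum normal is purely craniocaudal: caliper direction undefined")
  d / nd
}

# bilinear sample of a 2D mask (as 0/1) at continuous voxel coords
sample_mask <- function(mask, ix, iy) {
  nx <- nrow(mask); ny <- ncol(mask)
  ix <- clamp(ix, 1, nx); iy <- clamp(iy, 1, ny)
  i0 <- pmin(floor(ix), nx - 1L); fi <- ix - i0
  j0 <- pmin(floor(iy), ny - 1L); fj <- iy - j0
  mv <- as.numeric(mask)
  at <- function(i, j) mv[(j - 1) * nx + i]
  at(i0, j0) * (1 - fi) * (1 - fj) + at(i0 + 1, j0) * fi * (1 - fj) +
    at(i0, j0 + 1) * (1 - fi) * fj + at(i0 + 1, j0 + 1) * fi * fj
}

#' Caliper of one axial mask slice
#'
#' Longest chord of the slice mask along the in-plane projection of the
#' septum normal. Chords are scanned on parallel lines offset at quarter
#' voxel pitch; the mask boundary is located by linear interpolation of
#' the bilinearly sampled mask, giving sub-voxel endpoints.
#'
#' @param mask_slice 2D logical matrix.
#' @param septum a `septum_plane` (only the normal's in-plane projection
#'   is used).
#' @param spacing in-plane spacing (mm), length 2.
#' @param slice_z world z (mm) of the slice, stored in the endpoints.
#' @param slice_index slice number, stored in the result.
#' @param origin in-plane world origin (mm).
#' @return a `caliper` (`slice_index`, 2 x 3 `endpoints` in mm,
#'   `length_mm`) or `NULL` for an empty slice.
#' @export
slice_caliper <- function(mask_slice, septum, spacing, slice_z,
                          slice_index = NA_integer_, origin = c(0, 0)) {
  if (!any(mask_slice)) return(NULL)
  d <- in_plane_direction(septum)
  tv <- c(-d[2], d[1])
  ij <- which(mask_slice, arr.ind = TRUE)
  pos <- cbind((ij[, 1] - 0.5) * spacing[1] + origin[1],
               (ij[, 2] - 0.5) * spacing[2] + origin[2])
  u <- pos %*% d            # along measurement direction
  v <- pos %*% tv           # across scan lines
  step <- 0.25 * min(spacing)
  offs <- seq(min(v) - step, max(v) + step, by = step)
  ss <- seq(min(u) - 2 * step, max(u) + 2 * step, by = step)
  # sample grid: rows = scan lines, cols = positions along the line
  PX <- outer(offs * tv[1], ss * d[1], `+`)
  PY <- outer(offs * tv[2], ss * d[2], `+`)
  V <- sample_mask(mask_slice, (PX - origin[1]) / spacing[1] + 0.5,
                   (PY - origin[2]) / spacing[2] + 0.5)
  V <- matrix(V, nrow = length(offs))
  best <- 0; best_line <- NA; best_s <- c(NA, NA)
  for (r in seq_len(nrow(V))) {
    inside <- V[r, ] >= 0.5
    if (!any(inside)) next
    runs <- rle(inside)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (q in which(runs$values)) {
      a <- starts[q]; b <- ends[q]
      s0 <- ss[a]; s1 <- ss[b]
      # sub-voxel refinement of both crossings
      if (a > 1) {
        f <- (0.5 - V[r, a - 1]) / (V[r, a] - V[r, a - 1])
        s0 <- ss[a - 1] + f * step
      }
      if (b < length(ss)) {
        f <- (0.5 - V[r, b]) / (V[r, b + 1] - V[r, b])
        s1 <- ss[b] + f * step
      }
      if (s1 - s0 > best) {
        best <- s1 - s0; best_line <- offs[r]; best_s <- c(s0, s1)
      }
    }
  }
  if (best <= 0) return(NULL)
  p1 <- best_s[1] * d + best_line * tv
  p2 <- best_s[2] * d + best_line * tv
  structure(list(
    slice_index = slice_index,
    endpoints = rbind(c(p1, slice_z), c(p2, slice_z)),
    length_mm = best
  ), class = "caliper")
}

#' Radial contour profile of a mask slice and its degree-10 fit
#'
#' Samples the contour as the maximal radius of the mask per angle around
#' the given centroid (for non-star-shaped slices this takes the outermost
#' boundary) and fits a 10th-order polynomial over the angle by least
#' squares.
#'
#' @param mask_slice 2D logical matrix.
#' @param centroid in-plane voxel coordinates (continuous, 1-based) of the
#'   profile centre, typically the chamber seed.
#' @param spacing in-plane spacing (mm).
#' @param n_angles number of uniformly spaced angles (>= 64).
#' @param degree polynomial degree.
#' @return a `contour_profile`: `angles`, `radii_mm`, `coefficients`
#'   (increasing powers of the scaled angle `x = (angle - pi) / pi`),
#'   `residual_rms_mm`.
#' @export
fit_contour_profile <- function(mask_slice, centroid, spacing,
                                n_angles = 72L, degree = 10L) {
  if (sum(mask_slice) < 10) stop("mask slice has too few pixels for a contour fit")
  nx <- nrow(mask_slice); ny <- ncol(mask_slice)
  angles <- (seq_len(n_angles) - 1) / n_angles * 2 * pi
  rmax_mm <- sqrt(sum((c(nx, ny) * spacing)^2))
  step <- 0.25 * min(spacing)
  rs <- seq(0, rmax_mm, by = step)
  PX <- centroid[1] + outer(cos(angles) / spacing[1], rs)
  PY <- centroid[2] + outer(sin(angles) / spacing[2], rs)
  V <- matrix(sample_mask(mask_slice, PX, PY), nrow = n_angles)
  radii <- vapply(seq_len(n_angles), function(a) {
    inside <- which(V[a, ] >= 0.5)
    if (!length(inside)) return(0)
    b <- max(inside)
    r <- rs[b]
    if (b < length(rs)) {
      f <- (0.5 - V[a, b]) / (V[a, b + 1] - V[a, b])
      r <- rs[b] + f * step
    }
    r
  }, numeric(1))
  x <- (angles - pi) / pi
  X <- outer(x, 0:degree, `^`)
  fit <- stats::lm.fit(X, radii)
  structure(list(
    angles = angles,
    radii_mm = radii,
    coefficients = unname(fit$coefficients),
    residual_rms_mm = sqrt(mean(fit$residuals^2)),
    degree = degree
  ), class = "contour_profile")
}

# evaluate a contour_profile's polynomial on scaled angles x in [-1, 1]
profile_poly_eval <- function(profile, x) {
  drop(outer(x, 0:profile$degree, `^`) %*% profile$coefficients)
}

# significant concave notch: a local minimum of the fitted profile whose
# depth below the flanking maxima exceeds notch_frac * mean radius and an
# absolute floor (the degree-10 fit wiggles on millimetre-sized blobs)
profile_has_notch <- function(profile, notch_frac = 0.25, notch_min_mm = 2) {
  xs <- seq(-1, 1, length.out = 256)
  p <- profile_poly_eval(profile, xs)
  mins <- which(diff(sign(diff(p))) > 0) + 1L
  if (!length(mins)) return(FALSE)
  mean_r <- mean(profile$radii_mm)
  for (m in mins) {
    left <- if (m > 1) max(p[1:(m - 1)]) else p[1]
    right <- if (m < length(p)) max(p[(m + 1):length(p)]) else p[length(p)]
    depth <- min(left, right) - p[m]
    if (depth > notch_frac * mean_r && depth > notch_min_mm) return(TRUE)
  }
  FALSE
}

#' Locate the atrioventricular valve along the slice stack
#'
#' Two complementary signals mark slices as atrial, working cranially from
#' the maximal-caliper slice: (1) the caliper length trend - ventricular
#' cross-sections taper towards the valve, so a sustained re-increase of
#' the caliper length beyond `rise_frac` of the running minimum marks the
#' atrium, with the valve placed at the running minimum; (2) a significant
#' concave notch in the fitted contour profile, the waist where a slice
#' cuts both ventricle and atrium. Isolated calipers departing from the
#' local trend by more than `outlier_factor` are excluded as outliers.
#' When no valve evidence exists the full range is retained.
#'
#' @param slices slice indices (ascending, caudal to cranial).
#' @param lengths caliper length (mm) per slice (`NA` where absent).
#' @param profiles list of `contour_profile` (or `NULL`) per slice.
#' @param rise_frac trend re-increase fraction marking the atrium.
#' @param rise_min_mm absolute floor (mm) on that re-increase, so that
#'   millimetre-scale fluctuations of the tiny cross-sections near the
#'   chamber poles are not mistaken for an atrium.
#' @param notch_frac notch depth fraction (of mean radius).
#' @param notch_min_mm absolute notch depth floor (mm).
#' @param outlier_factor local-trend departure factor for single-slice
#'   exclusion.
#' @return list with `valve_slice` (most cranial non-atrial slice),
#'   `atrial_slices`, `outlier_slices`.
#' @export
find_valve_cutoff <- function(slices, lengths, profiles = NULL,
                              rise_frac = 0.15, rise_min_mm = 5,
                              notch_frac = 0.25, notch_min_mm = 2,
                              outlier_factor = 1.5) {
  ok <- !is.na(lengths)
  if (sum(ok) < 5) {
    return(list(valve_slice = max(slices[ok]), atrial_slices = integer(),
                outlier_slices = integer()))
  }
  slices_ok <- slices[ok]
  len_ok <- lengths[ok]
  n <- length(slices_ok)
  # single-slice outliers vs the running median of neighbours
  med <- stats::runmed(len_ok, k = 5, endrule = "median")
  outliers <- slices_ok[len_ok > outlier_factor * med | len_ok < med / outlier_factor]
  imax <- which.max(ifelse(slices_ok %in% outliers, -Inf, len_ok))
  atrial <- integer()
  valve <- slices_ok[n]
  if (imax < n) {
    run_min <- len_ok[imax]
    valve_i <- n
    for (t in (imax + 1):n) {
      if (len_ok[t] < run_min) run_min <- len_ok[t]
      notch <- FALSE
      # the notch signal is only meaningful on slices wide enough to hold
      # an atrium; small polar caps are left to the trend rule
      if (!is.null(profiles) && len_ok[t] >= 0.5 * len_ok[imax]) {
        pr <- profiles[[which(slices == slices_ok[t])]]
        if (!is.null(pr)) notch <- profile_has_notch(pr, notch_frac, notch_min_mm)
      }
      rise <- len_ok[t] - run_min
      if ((rise > rise_frac * run_min && rise > rise_min_mm) || notch) {
        atrial <- slices_ok[t:n]
        valve_i <- t - 1L
        break
      }
    }
    valve <- slices_ok[valve_i]
  }
  list(valve_slice = valve, atrial_slices = atrial,
       outlier_slices = setdiff(outliers, atrial))
}

#' Maximal calipers and the RV/LV diameter ratio
#'
#' Per chamber, the admissible calipers are those on slices between the
#' apex (most caudal measured slice) and the estimated valve, excluding
#' outlier slices; the chamber diameter is their maximum. The ratio
#' divides the RV maximum by the LV maximum; the maxima may come from
#' different craniocaudal levels. A chamber without admissible calipers
#' produces a flagged result without a ratio.
#'
#' @param rv_calipers,lv_calipers lists of `caliper` objects.
#' @param rv_valve,lv_valve valve results from [find_valve_cutoff()] (or
#'   `NULL` to admit every slice).
#' @return an `rvlv_result`: `rv`, `lv` (selected calipers), `ratio`,
#'   `valve_slice_rv`, `valve_slice_lv`, `flags`.
#' @export
select_max_and_ratio <- function(rv_calipers, lv_calipers,
                                 rv_valve = NULL, lv_valve = NULL) {
  pick <- function(calipers, valve) {
    calipers <- Filter(Negate(is.null), calipers)
    if (!length(calipers)) return(NULL)
    sl <- vapply(calipers, `[[`, numeric(1), "slice_index")
    admissible <- rep(TRUE, length(calipers))
    if (!is.null(valve)) {
      admissible <- sl <= valve$valve_slice & !(sl %in% valve$outlier_slices) &
        !(sl %in% valve$atrial_slices)
    }
    if (!any(admissible)) return(NULL)
    lens <- vapply(calipers, `[[`, numeric(1), "length_mm")
    calipers[admissible][[which.max(lens[admissible])]]
  }
  rv <- pick(rv_calipers, rv_valve)
  lv <- pick(lv_calipers, lv_valve)
  flags <- character()
  if (is.null(rv)) flags <- c(flags, "caliper_failed_rv")
  if (is.null(lv)) flags <- c(flags, "caliper_failed_lv")
  structure(list(
    rv = rv, lv = lv,
    ratio = if (!is.null(rv) && !is.null(lv)) rv$length_mm / lv$length_mm else NULL,
    valve_slice_rv = if (!is.null(rv_valve)) rv_valve$valve_slice else NA_integer_,
    valve_slice_lv = if (!is.null(lv_valve)) lv_valve$valve_slice else NA_integer_,
    flags = flags
  ), class = "rvlv_result")
}

#' @export
print.rvlv_result <- function(x, ...) {
  if (!is.null(x$ratio)) {
    cat(sprintf("RV/LV result: RV %.1f mm (slice %d), LV %.1f mm (slice %d), ratio %.3f\n",
                x$rv$length_mm, x$rv$slice_index,
                x$lv$length_mm, x$lv$slice_index, x$ratio))
  } else {
    cat("RV/LV result: no ratio (flags:", paste(x$flags, collapse = ", "), ")\n")
  }
  invisible(x)
}

# all per-slice calipers and profiles of a chamber mask
chamber_calipers <- function(vol, mask, septum, seeds = NULL) {
  m <- if (inherits(mask, "chamber_mask")) mask$mask else mask
  d <- dim(m)
  zs <- axis_coords(vol, 3)
  slices <- which(apply(m, 3, any))
  calipers <- vector("list", length(slices))
  profiles <- vector("list", length(slices))
  for (q in seq_along(slices)) {
    k <- slices[q]
    ms <- m[, , k]
    calipers[[q]] <- slice_caliper(ms, septum, vol$spacing[1:2], zs[k],
                                   slice_index = k,
                                   origin = vol$origin[1:2])
    if (sum(ms) >= 10) {
      ij <- which(ms, arr.ind = TRUE)
      cen <- colMeans(ij)
      if (!is.null(seeds) && k %in% seeds$slice) {
        s <- seeds[seeds$slice == k, ][1, ]
        cen <- c(s$i, s$j)
      }
      profiles[[q]] <- tryCatch(
        fit_contour_profile(ms, cen, vol$spacing[1:2]),
        error = function(e) NULL)
    }
  }
  list(slices = slices,
       lengths = vapply(seq_along(slices), function(q)
         if (is.null(calipers[[q]])) NA_real_ else calipers[[q]]$length_mm,
         numeric(1)),
       calipers = calipers, profiles = profiles)
}
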