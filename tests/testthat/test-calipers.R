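# Chord measurement, contour profiles, valve exclusion and the ratio.

plane_with_normal <- function(nrm) {
  structure(list(point = c(0, 0, 0), normal = nrm / sqrt(sum(nrm^2)),
                 score = 10, scale_mm = 3, low_confidence = FALSE),
            class = "septum_plane")
}

filled_ellipse <- function(a_mm, b_mm, spacing = c(1, 1), dim = c(80, 70),
                           angle = 0) {
  xs <- (seq_len(dim[1]) - 0.5) * spacing[1] - dim[1] * spacing[1] / 2
  ys <- (seq_len(dim[2]) - 0.5) * spacing[2] - dim[2] * spacing[2] / 2
  th <- angle * pi / 180
  U <- outer(xs * cos(th), ys * sin(th), `+`)
  V <- outer(-xs * sin(th), ys * cos(th), `+`)
  (U / a_mm)^2 + (V / b_mm)^2 <= 1
}

test_that("rectangle and ellipse chords match closed forms", {
  rect <- matrix(FALSE, 60, 40)
  rect[11:50, 11:30] <- TRUE      # 40 x 20 voxels at 1 mm
  cal <- slice_caliper(rect, plane_with_normal(c(1, 0, 0)), c(1, 1),
                       slice_z = 5, slice_index = 1L)
  expect_lt(abs(cal$length_mm - 40), 0.5)
  expect_equal(cal$endpoints[1, 3], 5)
  expect_equal(sqrt(sum((cal$endpoints[2, ] - cal$endpoints[1, ])^2)),
               cal$length_mm, tolerance = 1e-6)
  # chord direction parallel to the in-plane septum normal
  dirv <- (cal$endpoints[2, 1:2] - cal$endpoints[1, 1:2]) / cal$length_mm
  expect_equal(abs(sum(dirv * c(1, 0))), 1, tolerance = 1e-6)

  # ellipse semi-axes 25/15 mm, direction 30 degrees off the major axis:
  # the maximal chord along unit d (over all parallel lines) runs through
  # the centre, with length 2 / sqrt(d' diag(1/a^2, 1/b^2) d)
  ell <- filled_ellipse(25, 15)
  d30 <- c(cos(pi / 6), sin(pi / 6))
  cal2 <- slice_caliper(ell, plane_with_normal(c(d30, 0)), c(1, 1),
                        slice_z = 0, slice_index = 1L)
  closed <- 2 / sqrt(d30[1]^2 / 25^2 + d30[2]^2 / 15^2)
  expect_lt(abs(cal2$length_mm - closed), 0.5)
})

test_that("empty slices and craniocaudal normals are handled", {
  empty <- matrix(FALSE, 20, 20)
  expect_null(slice_caliper(empty, plane_with_normal(c(1, 0, 0)), c(1, 1), 0))
  disk <- filled_ellipse(8, 8, dim = c(30, 30))
  expect_error(slice_caliper(disk, plane_with_normal(c(0, 0, 1)), c(1, 1), 0),
               "craniocaudal")
})

test_that("contour profiles reproduce analytic radii and independent least squares", {
  disk <- filled_ellipse(12, 12, dim = c(40, 40))
  pr <- fit_contour_profile(disk, c(20.5, 20.5), c(1, 1))
  expect_lt(pr$residual_rms_mm, 0.2)
  xs <- seq(-1, 1, length.out = 128)
  vals <- rvlvcad:::profile_poly_eval(pr, xs)
  expect_lt(max(abs(vals - 12)), 0.5)
  expect_false(rvlvcad:::profile_has_notch(pr))

  ell <- filled_ellipse(20, 12, dim = c(60, 50))
  pre <- fit_contour_profile(ell, c(30.5, 25.5), c(1, 1))
  # analytic polar radius of an axis-aligned ellipse about its centre
  analytic <- function(th) 1 / sqrt((cos(th) / 20)^2 + (sin(th) / 12)^2)
  rel_rms <- sqrt(mean((pre$radii_mm - analytic(pre$angles))^2)) /
    mean(analytic(pre$angles))
  expect_lt(rel_rms, 0.02)

  # the fit must be the least-squares minimiser: compare with an
  # independent normal-equations solve
  X <- outer((pre$angles - pi) / pi, 0:10, `^`)
  ref <- solve(crossprod(X), crossprod(X, pre$radii_mm))
  fitted_pkg <- X %*% pre$coefficients
  fitted_ref <- X %*% ref
  expect_lt(max(abs(fitted_pkg - fitted_ref)), 1e-6)
  rms_ref <- sqrt(mean((pre$radii_mm - fitted_ref)^2))
  expect_equal(pre$residual_rms_mm, rms_ref, tolerance = 1e-6)

  expect_error(fit_contour_profile(matrix(FALSE, 10, 10), c(5, 5), c(1, 1)),
               "too few")
})

test_that("a peanut-shaped slice exhibits a significant notch", {
  two <- filled_ellipse(12, 12, dim = c(70, 40)) |
    filled_ellipse(12, 12, dim = c(70, 40), angle = 0) [c(16:70, 1:15), ]
  pr <- fit_contour_profile(two, c(28, 20.5), c(1, 1))
  expect_true(rvlvcad:::profile_has_notch(pr, notch_frac = 0.2))
})

test_that("valve detection retains the full range without atria", {
  st <- test_case_stages("noatrium", atrium_scale = 0, noise_sigma = 0)
  rv <- segment_chamber(st$ph$volume, st$rv_seeds, st$septum)
  cc <- rvlvcad:::chamber_calipers(st$ph$volume, rv, st$septum, st$rv_seeds)
  v <- find_valve_cutoff(cc$slices, cc$lengths, cc$profiles)
  expect_equal(v$valve_slice, max(cc$slices))
  expect_length(v$atrial_slices, 0)
})

test_that("atrial slices are excluded and the maximum stays ventricular", {
  st <- test_case_stages("atrium", atrium_scale = 1, noise_sigma = 0)
  rv <- segment_chamber(st$ph$volume, st$rv_seeds, st$septum)
  cc <- rvlvcad:::chamber_calipers(st$ph$volume, rv, st$septum, st$rv_seeds)
  v <- find_valve_cutoff(cc$slices, cc$lengths, cc$profiles)
  res <- select_max_and_ratio(cc$calipers, cc$calipers, v, v)
  expect_true(res$rv$slice_index %in% st$ph$truth$rv_slices)
  # slices holding only atrium lie beyond the cutoff
  beyond_vent <- cc$slices[cc$slices > max(st$ph$truth$rv_slices) + 1]
  expect_true(all(beyond_vent > v$valve_slice))
})

test_that("an injected single-slice outlier is excluded by the trend rule", {
  slices <- 1:15
  lengths <- 2 * 22 * sqrt(pmax(0, 1 - ((slices - 8) / 8)^2))
  lengths[lengths == 0] <- NA
  lengths[6] <- 2 * max(lengths, na.rm = TRUE)
  v <- find_valve_cutoff(slices, lengths)
  expect_true(6 %in% v$outlier_slices)
  res <- select_max_and_ratio(
    lapply(slices, function(s) if (is.na(lengths[s])) NULL else
      make_caliper(s, c(0, 0, s), c(lengths[s], 0, s))),
    lapply(slices, function(s) if (is.na(lengths[s])) NULL else
      make_caliper(s, c(0, 0, s), c(lengths[s], 0, s))),
    v, v)
  expect_false(res$rv$slice_index == 6)
})

test_that("ratio arithmetic and failure flags", {
  rv <- list(make_caliper(4, c(0, 0, 10), c(47.9, 0, 10)))
  lv <- list(make_caliper(6, c(0, 0, 15), c(44.6, 0, 15)))
  res <- select_max_and_ratio(rv, lv)
  expect_equal(res$ratio, 1.0740, tolerance = 1e-4)

  same <- list(make_caliper(1, c(0, 0, 0), c(50, 0, 0)))
  expect_equal(select_max_and_ratio(same, same)$ratio, 1.0, tolerance = 1e-12)

  res2 <- select_max_and_ratio(rv, list(NULL))
  expect_null(res2$ratio)
  expect_true("caliper_failed_lv" %in% res2$flags)
})
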