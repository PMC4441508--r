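# Phantom generator: geometry, ground truth, determinism.

test_that("spec validation rejects degenerate geometry", {
  expect_error(phantom_spec(chamber_separation = 0), "separation")
  expect_error(phantom_spec(chamber_separation = -5), "separation")
  expect_error(phantom_spec(rv_semi_axes = c(10, -1, 10)), "semi-axes")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma")
  expect_error(phantom_spec(spacing = c(1, 0, 1)), "spacing")
})

test_that("symmetric chambers give a unit ratio and disjoint masks", {
  ph <- generate_phantom(small_phantom_spec(
    rv_semi_axes = c(22, 21, 28), lv_semi_axes = c(22, 21, 28),
    atrium_scale = 0, noise_sigma = 0))
  expect_equal(ph$truth$true_ratio, 1.0, tolerance = 1e-9)
  expect_false(any(ph$truth$rv_mask & ph$truth$lv_mask))
  expect_equal(ph$truth$true_ratio,
               ph$truth$rv_axial_diameter_mm / ph$truth$lv_axial_diameter_mm,
               tolerance = 1e-9)
  expect_equal(sqrt(sum(ph$truth$septum_normal^2)), 1, tolerance = 1e-9)
})

test_that("true ratio matches a brute-force per-slice rasterisation oracle", {
  spec <- phantom_spec(rv_semi_axes = c(30, 25, 35),
                       lv_semi_axes = c(20, 25, 35),
                       volume_shape = c(110L, 110L, 40L),
                       septum_normal_angle = 0, noise_sigma = 0)
  ph <- generate_phantom(spec)
  # oracle: rasterise every axial cross-section ellipse at 0.1 mm and take
  # the longest x-direction pixel run, per chamber
  brute_diameter <- function(semi, center, zs) {
    best <- 0
    for (z in zs) {
      s2 <- 1 - ((z - center[3]) / semi[3])^2
      if (s2 <= 0) next
      a <- semi[1] * sqrt(s2); b <- semi[2] * sqrt(s2)
      vs <- seq(-b, b, by = 0.1)
      us <- seq(-a - 0.2, a + 0.2, by = 0.1)
      for (v in vs) {
        inside <- (us / a)^2 + (v / b)^2 <= 1
        best <- max(best, sum(inside) * 0.1)
      }
    }
    best
  }
  zs <- (seq_len(spec$volume_shape[3]) - 0.5) * spec$spacing[3]
  geo <- rvlvcad:::phantom_geometry(spec)
  rv_or <- brute_diameter(spec$rv_semi_axes, geo$rv_center,
                          zs[abs(zs - geo$rv_center[3]) < spec$rv_semi_axes[3]])
  lv_or <- brute_diameter(spec$lv_semi_axes, geo$lv_center,
                          zs[abs(zs - geo$lv_center[3]) < spec$lv_semi_axes[3]])
  expect_equal(ph$truth$rv_axial_diameter_mm, rv_or, tolerance = 0.01)
  expect_equal(ph$truth$lv_axial_diameter_mm, lv_or, tolerance = 0.01)
  expect_equal(ph$truth$true_ratio, rv_or / lv_or, tolerance = 0.01)
})

test_that("ground truth is invariant to septum rotation and scales with geometry", {
  base <- list(rv = c(26, 22, 30), lv = c(21, 20, 30))
  r0 <- generate_phantom(small_phantom_spec(
    rv_semi_axes = base$rv, lv_semi_axes = base$lv,
    septum_normal_angle = 0, noise_sigma = 0))$truth
  r30 <- generate_phantom(small_phantom_spec(
    rv_semi_axes = base$rv, lv_semi_axes = base$lv,
    septum_normal_angle = 30, noise_sigma = 0))$truth
  expect_equal(r0$true_ratio, r30$true_ratio, tolerance = 1e-6)
  k <- 0.8
  rs <- generate_phantom(small_phantom_spec(
    rv_semi_axes = k * base$rv, lv_semi_axes = k * base$lv,
    septum_normal_angle = 0, noise_sigma = 0))$truth
  expect_equal(rs$rv_axial_diameter_mm, k * r0$rv_axial_diameter_mm,
               tolerance = 0.02)
  expect_equal(rs$true_ratio, r0$true_ratio, tolerance = 1e-6)
})

test_that("analytic axial diameter matches trivial and numeric oracles", {
  # sphere: any normal, any dense slicing -> 2r
  expect_equal(ground_truth_axial_diameter(c(17, 17, 17), c(0, 0, 0),
                                           c(1, 0, 0),
                                           seq(-17, 17, by = 0.01)),
               34, tolerance = 1e-3)
  # principal chord along the normal through the centre slice
  expect_equal(ground_truth_axial_diameter(c(12, 30, 20), c(0, 0, 5),
                                           c(1, 0, 0), 5),
               24, tolerance = 1e-9)
  # numeric maximisation oracle at an oblique normal: dense search over
  # slice offset and chord offset in the septum frame
  semi <- c(23, 18, 27); nrm <- c(cos(pi / 6), sin(pi / 6), 0)
  zs <- seq(-30, 30, by = 0.05)
  oracle <- 0
  for (z in zs) {
    s2 <- 1 - (z / semi[3])^2
    if (s2 <= 0) next
    a <- semi[1] * sqrt(s2); b <- semi[2] * sqrt(s2)
    for (v in seq(-b, b, length.out = 301)) {
      chord <- 2 * a * sqrt(max(0, 1 - (v / b)^2))
      oracle <- max(oracle, chord)
    }
  }
  expect_equal(ground_truth_axial_diameter(semi, c(0, 0, 0), nrm, zs),
               oracle, tolerance = 0.01)
  # undefined direction for a purely craniocaudal normal
  expect_error(ground_truth_axial_diameter(semi, c(0, 0, 0), c(0, 0, 1), 0),
               "craniocaudal")
})

test_that("voxelised masks agree with analytic membership at fine spacing", {
  spec <- phantom_spec(rv_semi_axes = c(18, 16, 20), lv_semi_axes = c(16, 15, 20),
                       spacing = c(0.7, 0.7, 1), volume_shape = c(128L, 128L, 56L),
                       atrium_scale = 0, noise_sigma = 0)
  ph <- generate_phantom(spec)
  geo <- rvlvcad:::phantom_geometry(spec)
  d <- spec$volume_shape
  xs <- (seq_len(d[1]) - 0.5) * spec$spacing[1]
  ys <- (seq_len(d[2]) - 0.5) * spec$spacing[2]
  zs <- (seq_len(d[3]) - 0.5) * spec$spacing[3]
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)
  analytic <- rvlvcad:::ellipsoid_value(X, Y, Z, geo$rv_center,
                                        spec$rv_semi_axes, geo$frame) <= 1
  expect_gte(dice_coef(ph$truth$rv_mask, analytic), 0.99)
})

test_that("generation is deterministic and rejects bad noise seeds gracefully", {
  s <- small_phantom_spec(noise_sigma = 12, rng_seed = 42L)
  a <- generate_phantom(s); b <- generate_phantom(s)
  expect_identical(a$volume$voxels, b$volume$voxels)
  c <- generate_phantom(small_phantom_spec(noise_sigma = 12, rng_seed = 43L))
  expect_false(identical(a$volume$voxels, c$volume$voxels))
  # the generator must not disturb the caller's RNG stream
  set.seed(7); before <- runif(1)
  set.seed(7); invisible(generate_phantom(small_phantom_spec(noise_sigma = 5)))
  expect_identical(runif(1), before)
})

test_that("phantom specs round-trip through the plain-text format", {
  spec <- small_phantom_spec(septum_normal_angle = 22.5, noise_sigma = 7.25,
                             rng_seed = 99L)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_phantom_spec(spec, path)
  back <- read_phantom_spec(path)
  expect_equal(unclass(back), unclass(spec), tolerance = 1e-12)
})
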