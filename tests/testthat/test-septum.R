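# Hessian analysis, plate score, and septum plane estimation.

# dark axis-aligned slab between bright half-spaces, unblurred (the
# Gaussian-derivative scale provides the smoothing)
slab_volume <- function(angle_deg = 0, thickness = 8, pool = 300, slab = 40,
                        spacing = c(0.5, 0.5, 0.5), dim = c(80, 72, 40)) {
  th <- angle_deg * pi / 180
  xs <- (seq_len(dim[1]) - 0.5) * spacing[1]
  ys <- (seq_len(dim[2]) - 0.5) * spacing[2]
  cx <- mean(xs); cy <- mean(ys)
  u <- outer((xs - cx) * cos(th), (ys - cy) * sin(th), `+`)
  sl <- ifelse(abs(u) <= thickness / 2, slab, pool)
  vox <- array(rep(sl, dim[3]), dim)
  ct_volume(vox, spacing)
}

# closed-form second derivative at the centre of a Gaussian-blurred slab
slab_center_d2 <- function(depth, thickness, sigma) {
  h <- thickness / 2
  2 * depth * (h / sigma) * stats::dnorm(h / sigma) / sigma^2
}

test_that("vectorised symmetric eigenvalues match base eigen()", {
  set.seed(31)
  for (r in 1:25) {
    A <- matrix(rnorm(9), 3); A <- (A + t(A)) / 2
    H <- list(xx = A[1, 1], yy = A[2, 2], zz = A[3, 3],
              xy = A[1, 2], xz = A[1, 3], yz = A[2, 3])
    ev <- rvlvcad:::symm3_eigenvalues(lapply(H, function(v) array(v, c(1, 1, 1))))
    got <- c(ev$l1, ev$l2, ev$l3)
    ref <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sort(got), sort(ref), tolerance = 1e-10)
    expect_true(all(diff(abs(got)) <= 1e-10))  # sorted by magnitude
    v1 <- rvlvcad:::symm3_eigenvector(lapply(H, function(v) array(v, c(1, 1, 1))),
                                      array(ev$l1, c(1, 1, 1)))
    v1 <- c(v1$x, v1$y, v1$z)
    ref_v <- eigen(A, symmetric = TRUE)$vectors[, which.max(abs(ref))]
    expect_equal(abs(sum(v1 * ref_v)), 1, tolerance = 1e-8)
  }
})

test_that("a constant volume has an identically zero plate score", {
  vol <- ct_volume(array(120, c(30, 30, 20)), c(1, 1, 1))
  f <- plate_score_field(vol, scale_mm = 3)
  expect_equal(max(abs(f$score)), 0, tolerance = 1e-8)
  expect_error(plate_score_field(vol, scale_mm = 0), "scale")
})

test_that("slab score matches the analytic 1-D second derivative within 2%", {
  vol <- slab_volume()
  f <- plate_score_field(vol, scale_mm = 3)
  # restrict to the interior (away from boundary padding effects)
  interior <- array(FALSE, dim(vol$voxels))
  interior[13:68, 13:60, 13:28] <- TRUE
  sc <- f$score; sc[!interior] <- -Inf
  best <- which.max(sc)
  idx <- arrayInd(best, dim(vol$voxels))[1, ]
  # arg-max on the slab mid-plane (|x - cx| small)
  cx <- mean((seq_len(80) - 0.5) * 0.5)
  expect_lt(abs((idx[1] - 0.5) * 0.5 - cx), 0.75)
  analytic <- slab_center_d2(depth = 260, thickness = 8, sigma = 3)
  expect_equal(f$score[best], analytic, tolerance = 0.02)
  nrm <- c(f$nx[best], f$ny[best], f$nz[best])
  expect_lt(angle_between_deg(nrm, c(1, 0, 0)), 2)
})

test_that("the slab response is equivariant under in-plane rotation", {
  f0 <- plate_score_field(slab_volume(0), scale_mm = 3)
  f30 <- plate_score_field(slab_volume(30), scale_mm = 3)
  interior <- array(FALSE, c(80, 72, 40)); interior[17:64, 17:56, 13:28] <- TRUE
  m0 <- max(f0$score[interior]); m30 <- max(f30$score[interior])
  expect_equal(m30, m0, tolerance = 0.03)
  sc <- f30$score; sc[!interior] <- -Inf
  best <- which.max(sc)
  nrm <- c(f30$nx[best], f30$ny[best], f30$nz[best])
  expect_lt(angle_between_deg(nrm, c(cos(pi / 6), sin(pi / 6), 0)), 2)
})

test_that("positive affine intensity maps leave the arg-max in place and scale the score", {
  vol <- slab_volume()
  vol2 <- ct_volume(2.5 * vol$voxels + 100, vol$spacing)
  f1 <- plate_score_field(vol, scale_mm = 3)
  f2 <- plate_score_field(vol2, scale_mm = 3)
  interior <- array(FALSE, dim(vol$voxels)); interior[13:68, 13:60, 13:28] <- TRUE
  s1 <- f1$score; s1[!interior] <- -Inf
  s2 <- f2$score; s2[!interior] <- -Inf
  expect_identical(which.max(s1), which.max(s2))
  expect_equal(max(s2), 2.5 * max(s1), tolerance = 1e-6)
})

test_that("the septum plane is recovered accurately on phantoms", {
  st <- test_case_stages()
  pl <- st$septum
  expect_lt(angle_between_deg(pl$normal, st$ph$truth$septum_normal), 5)
  pdist <- abs(sum((pl$point - st$ph$truth$septum_point) *
                     st$ph$truth$septum_normal))
  expect_lt(pdist, 2)
  expect_false(pl$low_confidence)
  # normal is oriented RV -> LV
  expect_gt(sum(pl$normal * (st$ph$truth$lv_center - st$ph$truth$rv_center)), 0)
})

test_that("swapping the seed lists flips the normal but not the plane", {
  st <- test_case_stages()
  swapped <- estimate_septum(st$ph$volume, st$lv_seeds, st$rv_seeds)
  expect_equal(swapped$point, st$septum$point, tolerance = 1e-9)
  expect_equal(swapped$normal, -st$septum$normal, tolerance = 1e-9)
})

test_that("coincident seeds give an empty-search-region error", {
  st <- test_case_stages()
  expect_error(estimate_septum(st$ph$volume, st$rv_seeds, st$rv_seeds),
               "coincide|nonempty|region")
})

test_that("a contrast-free septum raises the low-confidence flag", {
  ph <- cached("flat_phantom", generate_phantom(failure_phantom_spec("flat_septum")))
  det <- filter_by_anatomy_prior(detect_slices(ph$volume, test_detector()),
                                 ph$volume)
  sel <- cluster_and_select(det, ph$volume)
  pl <- estimate_septum(ph$volume,
                        seeds_from_cluster(sel$RV, ph$volume),
                        seeds_from_cluster(sel$LV, ph$volume))
  expect_true(pl$low_confidence)
})
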