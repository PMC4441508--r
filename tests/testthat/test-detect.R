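# Window classifier training, per-slice detection, anatomical pruning,
# cluster ranking and seed placement.

# bright-disk fixtures with known separability
disk_fixtures <- function(n = 8, spacing = c(1.5, 1.5), dim = c(96, 96),
                          noise = 15, seed = 5) {
  withr::with_seed(seed, {
    fixtures <- lapply(seq_len(n), function(i) {
      img <- matrix(rnorm(prod(dim), 40, noise), dim[1], dim[2])
      centers <- list(rv = c(45 + runif(1, -6, 6), 60 + runif(1, -6, 6)),
                      lv = c(95 + runif(1, -6, 6), 80 + runif(1, -6, 6)))
      boxes <- list()
      for (ch in c("rv", "lv")) {
        cc <- centers[[ch]]
        r <- if (ch == "rv") 22 else 19
        xs <- (seq_len(dim[1]) - 0.5) * spacing[1]
        ys <- (seq_len(dim[2]) - 0.5) * spacing[2]
        D <- outer((xs - cc[1])^2, (ys - cc[2])^2, `+`)
        img[D <= r^2] <- 340 + rnorm(sum(D <= r^2), 0, noise)
        boxes[[paste0(ch, "_box")]] <- c(cc - r, cc + r)
      }
      c(list(image = img, spacing = spacing), boxes)
    })
    negatives <- lapply(1:4, function(i)
      list(image = matrix(rnorm(prod(dim), 40, noise), dim[1], dim[2]),
           spacing = spacing))
    list(fixtures = fixtures, negatives = negatives)
  })
}

test_that("training is seeded, reproducible, and separates disk fixtures", {
  fx <- disk_fixtures()
  m1 <- train_detector(fx$fixtures, fx$negatives, seed = 3)
  m2 <- train_detector(fx$fixtures, fx$negatives, seed = 3)
  expect_identical(m1$rv$w, m2$rv$w)
  expect_identical(m1$lv$b, m2$lv$b)
  expect_gte(m1$rv$auc, 0.99)
  expect_gte(m1$lv$auc, 0.99)
  m3 <- train_detector(fx$fixtures, fx$negatives, seed = 4)
  expect_false(identical(m1$rv$w, m3$rv$w))
})

test_that("swapping chamber labels approximately swaps the models", {
  fx <- disk_fixtures()
  m <- train_detector(fx$fixtures, fx$negatives, seed = 3)
  swapped <- lapply(fx$fixtures, function(f) {
    tmp <- f$rv_box; f$rv_box <- f$lv_box; f$lv_box <- tmp; f
  })
  ms <- train_detector(swapped, fx$negatives, seed = 3)
  expect_gt(stats::cor(ms$rv$w, m$lv$w), 0.75)
  expect_gt(stats::cor(ms$lv$w, m$rv$w), 0.75)
})

test_that("degenerate zero-variance features are rejected", {
  fx <- disk_fixtures()
  flat <- lapply(fx$fixtures, function(f) { f$image[] <- 100; f })
  flatneg <- lapply(fx$negatives, function(f) { f$image[] <- 100; f })
  expect_error(train_detector(flat, flatneg, seed = 1), "degenerate|zero variance")
})

test_that("detector models survive serialisation", {
  m <- test_detector()
  path <- withr::local_tempfile(fileext = ".json")
  save_detector(m, path)
  back <- load_detector(path)
  expect_equal(back$rv$w, m$rv$w, tolerance = 1e-12)
  expect_equal(back$mu, m$mu, tolerance = 1e-12)
  expect_equal(back$config$window_mm, m$config$window_mm)
})

test_that("a heart-free volume yields no detections and scoring is deterministic", {
  lung <- ct_volume(array(-800, c(72, 72, 6)), c(1.5, 1.5, 2.5))
  det <- detect_slices(lung, test_detector())
  expect_equal(nrow(det), 0)

  st <- test_case_stages()
  det1 <- detect_slices(st$ph$volume, test_detector())
  det2 <- detect_slices(st$ph$volume, test_detector())
  expect_identical(det1, det2)
})

test_that("mid-ventricular detections overlap the true chamber boxes", {
  st <- test_case_stages()
  ph <- st$ph
  kc <- round(mean(ph$truth$rv_slices))
  for (ch in c("RV", "LV")) {
    msk <- if (ch == "RV") ph$truth$rv_mask else ph$truth$lv_mask
    ij <- which(msk[, , kc], arr.ind = TRUE)
    tb <- c(min(ij[, 1]), min(ij[, 2]), max(ij[, 1]), max(ij[, 2]))
    det <- st$det[st$det$chamber == ch & st$det$slice == kc, , drop = FALSE]
    expect_gte(nrow(det), 1)
    best <- det[which.max(det$score), ]
    iou <- rvlvcad:::box_iou(c(best$x0, best$y0, best$x1, best$y1), tb)
    expect_gte(iou, 0.5)
  }
})

test_that("the anatomy prior only ever removes detections", {
  st <- test_case_stages()
  raw <- detect_slices(st$ph$volume, test_detector())
  filt <- filter_by_anatomy_prior(raw, st$ph$volume)
  key <- function(d) paste(d$chamber, d$slice, d$x0, d$y0, d$x1, d$y1)
  expect_true(all(key(filt) %in% key(raw)))
  # explicit bound checks on synthetic rows
  fake <- raw[1, ]
  fake$x0 <- 1; fake$x1 <- dim(st$ph$volume$voxels)[1]  # ~165 mm wide
  expect_equal(nrow(filter_by_anatomy_prior(fake, st$ph$volume,
                                            max_size_mm = 110)), 0)
  edge <- raw[1, ]
  edge$x0 <- 1; edge$x1 <- 8  # centre in the outer margin
  expect_equal(nrow(filter_by_anatomy_prior(edge, st$ph$volume)), 0)
})

test_that("cluster ranking follows sum(scores) * count^alpha with cranial ties", {
  det <- data.frame(
    chamber = "RV",
    slice = c(1:10, 5L),
    x0 = 30, y0 = 30, x1 = 40, y1 = 40,
    cx = c(rep(50, 10), 120), cy = 50,
    score = c(rep(1, 10), 5))
  det$cx[11] <- 120  # isolated high-score detection far away
  vol <- ct_volume(array(0, c(110, 110, 12)), c(1.5, 1.5, 2.5))
  sel <- cluster_and_select(det, vol, bandwidth = 15, alpha = 0.5)
  # 10 * sqrt(10) = 31.6 beats 5 * 1
  expect_equal(nrow(sel$RV$members), 10)
  expect_equal(sel$RV$rank_score, 10 * sqrt(10), tolerance = 1e-9)
  # no detections at all -> flag, not an exception
  sel2 <- cluster_and_select(det[0, ], vol)
  expect_null(sel2$RV); expect_null(sel2$LV)
  expect_setequal(sel2$flags, c("detection_failed_rv", "detection_failed_lv"))
})

test_that("seeds snap from a dark trabecula to the adjacent bright pool", {
  vox <- array(40, c(40, 40, 5))
  vox[10:30, 10:30, ] <- 330       # pool
  vox[20, 20, ] <- 60              # dark trabecula at the box centre
  vol <- ct_volume(vox, c(1.5, 1.5, 2.5))
  cl <- structure(list(
    chamber = "RV",
    members = data.frame(chamber = "RV", slice = 3L, x0 = 10, y0 = 10,
                         x1 = 30, y1 = 30, cx = 29.25, cy = 29.25, score = 1),
    mode = c((20 - 0.5) * 1.5, (20 - 0.5) * 1.5, 6.25),
    rank_score = 1), class = "detection_cluster")
  seeds <- seeds_from_cluster(cl, vol)
  expect_equal(nrow(seeds), 1)
  expect_gt(vol$voxels[seeds$i[1], seeds$j[1], seeds$slice[1]], 300)

  # uniform pool: the seed stays at the box centre
  vox2 <- vox; vox2[20, 20, ] <- 330
  vol2 <- ct_volume(vox2, c(1.5, 1.5, 2.5))
  seeds2 <- seeds_from_cluster(cl, vol2)
  expect_equal(c(seeds2$i[1], seeds2$j[1]), c(20, 20))
})

test_that("phantom seeds land inside the chambers on ventricular slices", {
  st <- test_case_stages()
  ph <- st$ph
  for (ch in c("rv", "lv")) {
    seeds <- st[[paste0(ch, "_seeds")]]
    msk <- ph$truth[[paste0(ch, "_mask")]]
    vent <- seeds[seeds$slice %in% ph$truth[[paste0(ch, "_slices")]], ]
    hit <- mapply(function(i, j, k) msk[i, j, k], vent$i, vent$j, vent$slice)
    expect_gte(mean(hit), 0.95)
  }
})
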