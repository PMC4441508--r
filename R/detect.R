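# Per-slice ventricle detection.
#
# The detector scores fixed-size sliding windows on every axial slice with a
# regularised linear model over gradient-orientation-histogram and
# block-intensity features, suppresses non-maximal windows, and tightens
# each surviving window to the bright blood-pool component it contains.
# Detections are then pruned by anatomical priors, linked across slices by
# mean-shift clustering in world coordinates, and the best-ranked cluster
# per chamber yields one seed point per slice.

#' Detector configuration
#'
#' @param window_mm sliding-window side length (mm); sized to enclose a
#'   ventricle cross-section.
#' @param grid_n windows are resampled to `grid_n x grid_n` before feature
#'   extraction, making features independent of voxel spacing.
#' @param stride_mm sliding-window stride (mm).
#' @param score_threshold minimum linear score for a window to be kept.
#' @param nms_iou per-slice non-maximum suppression overlap threshold.
#' @param ridge_lambda ridge penalty used when training.
#' @return list of detector settings.
#' @export
detector_config <- function(window_mm = 80, grid_n = 16L, stride_mm = 6,
                            score_threshold = 0, nms_iou = 0.3,
                            ridge_lambda = 1e-2) {
  list(window_mm = window_mm, grid_n = as.integer(grid_n),
       stride_mm = stride_mm, score_threshold = score_threshold,
       nms_iou = nms_iou, ridge_lambda = ridge_lambda)
}

# Bilinear patch sampling: one grid_n^2 patch per window centre.
# Returns an n x grid_n^2 matrix (first grid axis fastest).
sample_patches <- function(slice, spacing_xy, centers, window_mm, grid_n) {
  nx <- nrow(slice); ny <- ncol(slice)
  step <- window_mm / grid_n
  offs <- (seq_len(grid_n) - (grid_n + 1) / 2) * step
  oa <- rep(offs, times = grid_n)
  ob <- rep(offs, each = grid_n)
  PX <- outer(centers[, 1], oa, `+`)
  PY <- outer(centers[, 2], ob, `+`)
  ix <- clamp(PX / spacing_xy[1] + 0.5, 1, nx)
  iy <- clamp(PY / spacing_xy[2] + 0.5, 1, ny)
  i0 <- pmin(floor(ix), nx - 1L); fi <- ix - i0
  j0 <- pmin(floor(iy), ny - 1L); fj <- iy - j0
  sv <- as.numeric(slice)
  at <- function(i, j) sv[(j - 1) * nx + i]
  v <- at(i0, j0) * (1 - fi) * (1 - fj) + at(i0 + 1, j0) * fi * (1 - fj) +
    at(i0, j0 + 1) * (1 - fi) * fj + at(i0 + 1, j0 + 1) * fi * fj
  matrix(v, nrow = nrow(centers))
}

# Gradient-orientation histogram (8 signed bins x 2x2 cells, L2-normalised)
# plus 2x2 block mean intensities standardised within the window, so the
# intensity pattern (a central bright pool against its surroundings) is
# captured independently of the absolute contrast enhancement:
# 36 features per window.
window_features <- function(patches, grid_n) {
  n <- nrow(patches)
  g <- grid_n
  A <- array(patches, c(n, g, g))
  gx <- A[, 2:g, 2:g, drop = FALSE] - A[, 1:(g - 1), 2:g, drop = FALSE]
  gy <- A[, 2:g, 2:g, drop = FALSE] - A[, 2:g, 1:(g - 1), drop = FALSE]
  p <- (g - 1)^2
  gx <- matrix(gx, n, p); gy <- matrix(gy, n, p)
  mag <- sqrt(gx^2 + gy^2)
  bin <- pmin(floor((atan2(gy, gx) + pi) / (2 * pi) * 8) + 1L, 8L)
  # cell assignment of each gradient position (constant across windows)
  pa <- rep(seq_len(g - 1), times = g - 1)
  pb <- rep(seq_len(g - 1), each = g - 1)
  cell <- (pa > (g - 1) / 2) + 2 * (pb > (g - 1) / 2) + 1L
  P <- matrix(0, p, 4); P[cbind(seq_len(p), cell)] <- 1
  hog <- matrix(0, n, 32)
  for (k in 1:8) hog[, seq(k, 32, by = 8)] <- (mag * (bin == k)) %*% P
  hog <- hog / (sqrt(rowSums(hog^2)) + 1e-6)
  qa <- rep(seq_len(g), times = g)
  qb <- rep(seq_len(g), each = g)
  qcell <- (qa > g / 2) + 2 * (qb > g / 2) + 1L
  Q <- matrix(0, g^2, 4); Q[cbind(seq_len(g^2), qcell)] <- 1
  mu_w <- rowMeans(patches)
  sd_w <- sqrt(rowMeans((patches - mu_w)^2))
  ints <- ((patches %*% Q) / (g^2 / 4) - mu_w) / (sd_w + 1e-6)
  cbind(hog, ints)
}

slice_feature_matrix <- function(slice, spacing_xy, centers, config) {
  patches <- sample_patches(slice, spacing_xy, centers, config$window_mm,
                            config$grid_n)
  window_features(patches, config$grid_n)
}

ridge_fit <- function(X, y, lambda) {
  Xa <- cbind(1, X)
  p <- ncol(Xa)
  pen <- diag(c(0, rep(lambda * nrow(Xa), p - 1)), p)
  coef <- solve(crossprod(Xa) + pen, crossprod(Xa, y))
  list(b = coef[1], w = coef[-1])
}

# area under the ROC curve via the rank-sum statistic
roc_auc <- function(scores, labels) {
  pos <- scores[labels > 0]; neg <- scores[labels <= 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Train the per-chamber window classifiers
#'
#' Fits one regularised linear model per chamber on labelled axial slices.
#' Positive windows are sampled around each chamber's bounding-box centre
#' (with small jitters); negatives combine windows from heart-free slices,
#' displaced windows, and the opposite chamber's positives, so each model
#' learns to tell its chamber from both background and the other chamber.
#' Training is deterministic for a given seed.
#'
#' @param fixtures list of labelled slices, each
#'   `list(image, spacing, rv_box, lv_box)` where `image` is a 2D HU
#'   matrix, `spacing` the in-plane mm spacing, and the boxes are
#'   `c(x0, y0, x1, y1)` in mm (or `NULL` when the chamber is absent).
#' @param negatives list of heart-free slices, each `list(image, spacing)`.
#' @param config a [detector_config()].
#' @param seed integer seed for jitter/negative sampling.
#' @param holdout_frac fraction of windows held out to estimate the
#'   training AUC stored in the model.
#' @return a `detector_model` with standardisation constants, per-chamber
#'   weights, the score threshold, and held-out AUCs.
#' @export
train_detector <- function(fixtures, negatives, config = detector_config(),
                           seed = 1L, holdout_frac = 0.25) {
  if (!length(fixtures)) stop("no labelled fixtures given")
  with_seed(seed, {
    jit <- function() stats::runif(2, -4, 4)
    feats <- list(); labs <- list()
    box_center <- function(b) c((b[1] + b[3]) / 2, (b[2] + b[4]) / 2)
    for (fx in fixtures) {
      centers <- NULL; lab <- NULL
      for (ch in c("rv", "lv")) {
        b <- fx[[paste0(ch, "_box")]]
        if (is.null(b)) next
        cc <- box_center(b)
        pts <- t(vapply(1:4, function(i) cc + if (i == 1) c(0, 0) else jit(),
                        numeric(2)))
        centers <- rbind(centers, pts)
        lab <- c(lab, rep(toupper(ch), nrow(pts)))
      }
      # displaced negatives, away from both chambers
      ext <- dim(fx$image) * fx$spacing
      for (r in 1:4) {
        cand <- c(stats::runif(1, config$window_mm / 2, ext[1] - config$window_mm / 2),
                  stats::runif(1, config$window_mm / 2, ext[2] - config$window_mm / 2))
        boxes <- Filter(Negate(is.null), list(fx$rv_box, fx$lv_box))
        dmin <- min(vapply(boxes, function(b)
          sqrt(sum((cand - box_center(b))^2)), numeric(1)))
        if (dmin > 0.7 * config$window_mm) {
          centers <- rbind(centers, cand)
          lab <- c(lab, "NEG")
        }
      }
      F <- slice_feature_matrix(fx$image, fx$spacing, centers, config)
      feats[[length(feats) + 1L]] <- F
      labs[[length(labs) + 1L]] <- lab
    }
    for (ng in negatives) {
      ext <- dim(ng$image) * ng$spacing
      gx <- seq(config$window_mm / 2, ext[1] - config$window_mm / 2, length.out = 4)
      gy <- seq(config$window_mm / 2, ext[2] - config$window_mm / 2, length.out = 4)
      centers <- as.matrix(expand.grid(gx, gy))
      F <- slice_feature_matrix(ng$image, ng$spacing, centers, config)
      feats[[length(feats) + 1L]] <- F
      labs[[length(labs) + 1L]] <- rep("NEG", nrow(centers))
    }
    X <- do.call(rbind, feats)
    lab <- unlist(labs)
    if (sum(lab == "RV") < 8 || sum(lab == "LV") < 8 || sum(lab == "NEG") < 8)
      stop("too few training windows (need positives for both chambers and negatives)")
    mu <- colMeans(X)
    sd <- apply(X, 2, stats::sd)
    if (any(sd < 1e-12))
      stop("degenerate features: zero variance in training windows")
    Xs <- sweep(sweep(X, 2, mu), 2, sd, `/`)
    ho <- seq_len(nrow(Xs)) %in%
      sample(nrow(Xs), max(2L, floor(holdout_frac * nrow(Xs))))
    fit_ch <- function(chamber) {
      y <- ifelse(lab == chamber, 1, -1)
      fit <- ridge_fit(Xs[!ho, , drop = FALSE], y[!ho], config$ridge_lambda)
      sc <- Xs %*% fit$w + fit$b
      list(w = as.numeric(fit$w), b = fit$b,
           auc = roc_auc(sc[ho], y[ho]))
    }
    model <- list(version = 1L, config = config, mu = mu, sd = sd,
                  rv = fit_ch("RV"), lv = fit_ch("LV"),
                  threshold = config$score_threshold)
    class(model) <- "detector_model"
    model
  })
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf("detector_model v%d: window %g mm, %d features, held-out AUC RV %.3f / LV %.3f\n",
              x$version, x$config$window_mm, length(x$mu), x$rv$auc, x$lv$auc))
  invisible(x)
}

#' Save / load a detector model
#' @param model a `detector_model`
#' @param path JSON file path
#' @export
save_detector <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$config <- do.call(detector_config, m$config)
  class(m) <- "detector_model"
  m
}

# Otsu threshold of a numeric vector/matrix
otsu_threshold <- function(x, nbins = 128L) {
  r <- range(x)
  if (diff(r) <= 0) return(r[1])
  h <- tabulate(pmin(as.integer((x - r[1]) / diff(r) * nbins) + 1L, nbins), nbins)
  w <- cumsum(h)
  m <- cumsum(h * seq_len(nbins))
  tot <- w[nbins]; mt <- m[nbins]
  between <- (mt * w - m * tot)^2 / (w * (tot - w))
  between[!is.finite(between)] <- 0
  k <- which.max(between)
  r[1] + k / nbins * diff(r)
}

# Tighten a fixed-size window to the bright component it contains: Otsu
# threshold inside the window, region-grow from the brightest central
# pixel, return the component bounding box in voxel coordinates.
refine_box <- function(slice, spacing_xy, center_mm, window_mm) {
  nx <- nrow(slice); ny <- ncol(slice)
  half <- window_mm / 2
  i0 <- max(1L, floor((center_mm[1] - half) / spacing_xy[1] + 0.5))
  i1 <- min(nx, ceiling((center_mm[1] + half) / spacing_xy[1] + 0.5))
  j0 <- max(1L, floor((center_mm[2] - half) / spacing_xy[2] + 0.5))
  j1 <- min(ny, ceiling((center_mm[2] + half) / spacing_xy[2] + 0.5))
  sub <- slice[i0:i1, j0:j1]
  # threshold pool vs. myocardium among non-lung pixels, otherwise a
  # lung-containing window splits at lung/tissue and the whole heart fuses
  soft <- sub[sub > -200]
  if (length(soft) < 20) return(NULL)
  ci <- clamp(round(center_mm[1] / spacing_xy[1] + 0.5) - i0 + 1L, 1L, nrow(sub))
  cj <- clamp(round(center_mm[2] / spacing_xy[2] + 0.5) - j0 + 1L, 1L, ncol(sub))
  ri <- clamp(ci + (-2:2), 1L, nrow(sub)); rj <- clamp(cj + (-2:2), 1L, ncol(sub))
  core <- sub[ri, rj]
  w <- which(core == max(core), arr.ind = TRUE)[1, ]
  seed <- c(ri[w[1]], rj[w[2]])
  seed_val <- sub[seed[1], seed[2]]
  # cap the threshold relative to the seeded pool intensity: a window that
  # also catches a fragment of the brighter other chamber would otherwise
  # push Otsu above a poorly opacified pool and discard it entirely
  th <- otsu_threshold(soft)
  if (seed_val > 0) th <- min(th, 0.7 * seed_val)
  bw <- sub >= th
  if (!bw[seed[1], seed[2]]) return(NULL)
  comp <- matrix(FALSE, nrow(bw), ncol(bw))
  comp[seed[1], seed[2]] <- TRUE
  repeat {
    grown <- comp
    grown[-1, ] <- grown[-1, ] | comp[-nrow(comp), ]
    grown[-nrow(comp), ] <- grown[-nrow(comp), ] | comp[-1, ]
    grown[, -1] <- grown[, -1] | comp[, -ncol(comp)]
    grown[, -ncol(comp)] <- grown[, -ncol(comp)] | comp[, -1]
    grown <- grown & bw
    if (identical(grown, comp)) break
    comp <- grown
  }
  ij <- which(comp, arr.ind = TRUE)
  c(x0 = i0 + min(ij[, 1]) - 1L, y0 = j0 + min(ij[, 2]) - 1L,
    x1 = i0 + max(ij[, 1]) - 1L, y1 = j0 + max(ij[, 2]) - 1L)
}

box_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (ua <= 0) 0 else inter / ua
}

#' Detect ventricle candidates on every axial slice
#'
#' Scores sliding windows on each slice with both chamber models, keeps
#' windows above the score threshold, applies per-slice non-maximum
#' suppression, and tightens each surviving window to its bright
#' blood-pool component. Deterministic: the same volume and model always
#' yield the same detections.
#'
#' @param vol a [ct_volume()] in canonical orientation.
#' @param model a trained `detector_model`.
#' @return data frame of detections: `chamber`, `slice`, voxel-coordinate
#'   box `x0,y0,x1,y1`, window centre in mm `cx,cy`, and `score`.
#' @export
detect_slices <- function(vol, model) {
  config <- model$config
  d <- dim(vol$voxels)
  sp <- vol$spacing
  ext <- d[1:2] * sp[1:2]
  half <- config$window_mm / 2
  if (any(ext < config$window_mm))
    stop("volume cross-section smaller than the detector window")
  gx <- seq(half, ext[1] - half, by = config$stride_mm)
  gy <- seq(half, ext[2] - half, by = config$stride_mm)
  centers <- as.matrix(expand.grid(cx = gx, cy = gy))
  out <- list()
  for (k in seq_len(d[3])) {
    slice <- vol$voxels[, , k]
    F <- slice_feature_matrix(slice, sp[1:2], centers, config)
    Fs <- sweep(sweep(F, 2, model$mu), 2, model$sd, `/`)
    for (ch in c("RV", "LV")) {
      m <- if (ch == "RV") model$rv else model$lv
      sc <- as.numeric(Fs %*% m$w + m$b)
      keep <- which(sc > model$threshold)
      if (!length(keep)) next
      ord <- keep[order(sc[keep], decreasing = TRUE)]
      boxes <- cbind(centers[ord, 1] - half, centers[ord, 2] - half,
                     centers[ord, 1] + half, centers[ord, 2] + half)
      sel <- logical(length(ord))
      for (i in seq_along(ord)) {
        ok <- TRUE
        for (j in which(sel)) {
          if (box_iou(boxes[i, ], boxes[j, ]) > config$nms_iou) { ok <- FALSE; break }
        }
        sel[i] <- ok
      }
      for (i in which(sel)) {
        rb <- refine_box(slice, sp[1:2], centers[ord[i], ], config$window_mm)
        if (is.null(rb)) next
        out[[length(out) + 1L]] <- data.frame(
          chamber = ch, slice = k,
          x0 = rb[1], y0 = rb[2], x1 = rb[3], y1 = rb[4],
          cx = (rb[1] + rb[3]) / 2 * sp[1] - sp[1] / 2,
          cy = (rb[2] + rb[4]) / 2 * sp[2] - sp[2] / 2,
          score = sc[ord[i]])
      }
    }
  }
  if (!length(out))
    return(data.frame(chamber = character(), slice = integer(),
                      x0 = numeric(), y0 = numeric(), x1 = numeric(),
                      y1 = numeric(), cx = numeric(), cy = numeric(),
                      score = numeric()))
  do.call(rbind, out)
}

#' Prune detections inconsistent with cardiac anatomy
#'
#' Removes boxes whose physical size lies outside plausible chamber bounds,
#' whose centre falls in the outer margin of the slice, or whose mean
#' interior attenuation is below a blood-pool floor. The result is always
#' a subset of the input.
#'
#' @param detections output of [detect_slices()].
#' @param vol the volume the detections came from.
#' @param min_size_mm,max_size_mm admissible box side lengths (mm).
#' @param margin_frac excluded outer fraction of the slice per side.
#' @param hu_floor minimum mean interior HU; set well below normal pool
#'   enhancement so poorly-opacified ventricles are still detected.
#' @return filtered detections data frame.
#' @export
filter_by_anatomy_prior <- function(detections, vol, min_size_mm = 15,
                                    max_size_mm = 110, margin_frac = 0.1,
                                    hu_floor = 80) {
  if (!nrow(detections)) return(detections)
  sp <- vol$spacing
  d <- dim(vol$voxels)
  wmm <- (detections$x1 - detections$x0 + 1) * sp[1]
  hmm <- (detections$y1 - detections$y0 + 1) * sp[2]
  cx <- (detections$x0 + detections$x1) / 2
  cy <- (detections$y0 + detections$y1) / 2
  central <- cx >= margin_frac * d[1] & cx <= (1 - margin_frac) * d[1] &
    cy >= margin_frac * d[2] & cy <= (1 - margin_frac) * d[2]
  size_ok <- wmm >= min_size_mm & wmm <= max_size_mm &
    hmm >= min_size_mm & hmm <= max_size_mm
  mean_hu <- vapply(seq_len(nrow(detections)), function(i) {
    b <- detections[i, ]
    mean(vol$voxels[b$x0:b$x1, b$y0:b$y1, b$slice])
  }, numeric(1))
  detections[central & size_ok & mean_hu >= hu_floor, , drop = FALSE]
}

#' Link detections across slices and select the best cluster per chamber
#'
#' Detection box centres are clustered per chamber with [mean_shift_cluster()]
#' in world coordinates and ranked by
#' `sum(member scores) * (member count)^alpha`. The RV and LV clusters are
#' selected jointly: the pair maximising the summed rank subject to their
#' modes lying at least `min_separation_mm` apart, since the two ventricles
#' are distinct structures separated by the septum - this resolves the
#' occasional case where both chamber models peak on the same blood pool.
#' An empty chamber (or an unsatisfiable separation constraint) yields a
#' `detection_failed` flag rather than an error; rank ties go to the more
#' cranial cluster.
#'
#' @param detections filtered detections data frame.
#' @param vol the source volume.
#' @param bandwidth mean-shift bandwidth (mm).
#' @param alpha exponent on the member count in the ranking function.
#' @param min_separation_mm minimum distance between the selected RV and
#'   LV cluster modes.
#' @return `list(RV =, LV =, flags =)` where each chamber is a
#'   `detection_cluster` (`members` data frame, `mode` in mm, `rank_score`)
#'   or `NULL` when detection failed.
#' @export
cluster_and_select <- function(detections, vol, bandwidth = 15, alpha = 0.5,
                               min_separation_mm = 25) {
  res <- list(RV = NULL, LV = NULL, flags = character())
  ranked <- list(RV = NULL, LV = NULL)
  for (ch in c("RV", "LV")) {
    det <- detections[detections$chamber == ch, , drop = FALSE]
    if (!nrow(det)) next
    zc <- axis_coords(vol, 3)[det$slice]
    pts <- cbind(det$cx, det$cy, zc)
    ms <- mean_shift_cluster(pts, weights = pmax(det$score, 0) + 1e-3,
                             bandwidth = bandwidth)
    ranks <- vapply(ms, function(cl)
      sum(det$score[cl$members]) * length(cl$members)^alpha, numeric(1))
    mean_slice <- vapply(ms, function(cl) mean(det$slice[cl$members]), numeric(1))
    ord <- order(-ranks, mean_slice)
    ranked[[ch]] <- lapply(ord, function(b) structure(list(
      chamber = ch,
      members = det[ms[[b]]$members, , drop = FALSE],
      mode = ms[[b]]$mode,
      rank_score = ranks[b]
    ), class = "detection_cluster"))
  }
  if (!is.null(ranked$RV) && !is.null(ranked$LV)) {
    best <- NULL; best_sum <- -Inf
    for (a in ranked$RV) for (b in ranked$LV) {
      if (sqrt(sum((a$mode - b$mode)^2)) < min_separation_mm) next
      if (a$rank_score + b$rank_score > best_sum) {
        best_sum <- a$rank_score + b$rank_score
        best <- list(RV = a, LV = b)
      }
    }
    if (!is.null(best)) {
      res$RV <- best$RV; res$LV <- best$LV
      return(res)
    }
    # separation unsatisfiable: keep the stronger chamber, flag the other
    if (ranked$RV[[1]]$rank_score >= ranked$LV[[1]]$rank_score) {
      res$RV <- ranked$RV[[1]]
      res$flags <- "detection_failed_lv"
    } else {
      res$LV <- ranked$LV[[1]]
      res$flags <- "detection_failed_rv"
    }
    return(res)
  }
  for (ch in c("RV", "LV")) {
    if (is.null(ranked[[ch]]))
      res$flags <- c(res$flags, paste0("detection_failed_", tolower(ch)))
    else res[[ch]] <- ranked[[ch]][[1]]
  }
  res
}

#' Seed points from the selected cluster
#'
#' One seed per member slice, snapped to the brightest voxel within a small
#' in-plane neighbourhood so seeds land in the blood pool rather than on a
#' trabecula; sorted by slice. The in-plane position is the cluster mode
#' rather than each slice's own box centre: individual box centres drift
#' into the atria on peri-valvular slices, whereas the chamber's long axis
#' is craniocaudal so the mode stays inside the ventricle on every slice
#' that has one.
#'
#' @param cluster a `detection_cluster`.
#' @param vol the source volume.
#' @param snap_radius in-plane snapping radius (voxels).
#' @return data frame of seeds: `chamber`, `slice`, voxel indices `i`, `j`.
#' @export
seeds_from_cluster <- function(cluster, vol, snap_radius = 3L) {
  if (is.null(cluster) || !nrow(cluster$members)) stop("empty cluster")
  d <- dim(vol$voxels)
  mem <- cluster$members[order(cluster$members$slice), , drop = FALSE]
  mem <- mem[!duplicated(mem$slice), , drop = FALSE]
  mi <- round(cluster$mode[1] / vol$spacing[1] + 0.5)
  mj <- round(cluster$mode[2] / vol$spacing[2] + 0.5)
  seeds <- lapply(seq_len(nrow(mem)), function(r) {
    b <- mem[r, ]
    ci <- clamp(mi, 1L, d[1])
    cj <- clamp(mj, 1L, d[2])
    ri <- clamp(ci + (-snap_radius:snap_radius), 1L, d[1])
    rj <- clamp(cj + (-snap_radius:snap_radius), 1L, d[2])
    nb <- vol$voxels[ri, rj, b$slice]
    cand <- which(nb == max(nb), arr.ind = TRUE)
    # ties go to the candidate nearest the centre (then lowest index)
    dc <- (ri[cand[, 1]] - ci)^2 + (rj[cand[, 2]] - cj)^2
    w <- cand[which.min(dc), ]
    data.frame(chamber = cluster$chamber, slice = b$slice,
               i = ri[w[1]], j = rj[w[2]])
  })
  do.call(rbind, seeds)
}
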