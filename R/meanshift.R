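#' Mean-shift clustering of weighted 3D points
#'
#' Non-parametric mode seeking with a Gaussian kernel: every point ascends
#' to a mode of the weighted kernel density estimate by iterating the
#' kernel-weighted mean of all points until its displacement falls below
#' `tol`. Points whose modes lie within `bandwidth / 2` of each other are
#' merged into one cluster. Inputs are expected in millimetres so that the
#' single isotropic bandwidth is meaningful on anisotropic voxel grids.
#'
#' @param points n x 3 numeric matrix (mm).
#' @param weights nonnegative point weights (default equal).
#' @param bandwidth Gaussian kernel standard deviation (mm), > 0.
#' @param tol convergence threshold on the shift displacement (mm).
#' @param max_iter iteration cap.
#' @return list of clusters, each `list(mode, members, density)` where
#'   `members` are row indices into `points` and `mode` is the 3D position
#'   of the highest-density member mode.
#' @export
mean_shift_cluster <- function(points, weights = NULL, bandwidth,
                               tol = 1e-3, max_iter = 500L) {
  points <- rbind(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (!n) stop("points must be nonempty")
  if (!is.numeric(bandwidth) || length(bandwidth) != 1 || bandwidth <= 0)
    stop("bandwidth must be a single positive length (mm)")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0))
    stop("weights must be nonnegative, one per point")
  h2 <- 2 * bandwidth^2
  Y <- points
  active <- rep(TRUE, n)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    Ya <- Y[active, , drop = FALSE]
    # squared distances from active positions to all data points
    d2 <- outer(rowSums(Ya^2), rowSums(points^2), `+`) -
      2 * Ya %*% t(points)
    K <- exp(-pmax(d2, 0) / h2) * rep(weights, each = nrow(Ya))
    denom <- rowSums(K)
    newY <- (K %*% points) / denom
    shift <- sqrt(rowSums((newY - Ya)^2))
    Y[active, ] <- newY
    active[active] <- shift >= tol
  }
  # kernel density at each converged mode
  d2m <- outer(rowSums(Y^2), rowSums(points^2), `+`) - 2 * Y %*% t(points)
  dens <- rowSums(exp(-pmax(d2m, 0) / h2) * rep(weights, each = n))
  # merge modes within bandwidth/2, in point order (deterministic)
  cluster_of <- integer(n)
  reps <- list()
  for (i in seq_len(n)) {
    assigned <- 0L
    for (c in seq_along(reps)) {
      if (sqrt(sum((Y[i, ] - reps[[c]])^2)) < bandwidth / 2) { assigned <- c; break }
    }
    if (!assigned) {
      reps[[length(reps) + 1L]] <- Y[i, ]
      assigned <- length(reps)
    }
    cluster_of[i] <- assigned
  }
  lapply(seq_along(reps), function(c) {
    members <- which(cluster_of == c)
    best <- members[which.max(dens[members])]
    list(mode = as.numeric(Y[best, ]), members = members, density = dens[best])
  })
}
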