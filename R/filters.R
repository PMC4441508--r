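# Separable spatial filtering and Hessian analysis on anisotropic grids.
#
# All derivative filters are expressed per millimetre, not per voxel, so that
# downstream eigenvalue scores are in HU/mm^2 regardless of the grid spacing.

# Sampled Gaussian (derivative) kernel on a grid of pitch h mm.
# order 0 is normalised to unit sum; orders 1 and 2 are sampled from the
# continuous derivative and scaled by h so the discrete sum approximates the
# continuous convolution integral.
gauss_kernel <- function(sigma_mm, h_mm, order = 0L) {
  stopifnot(sigma_mm > 0, h_mm > 0)
  r <- max(1L, ceiling(4 * sigma_mm / h_mm))
  x <- (-r:r) * h_mm
  g <- exp(-x^2 / (2 * sigma_mm^2)) / (sqrt(2 * pi) * sigma_mm)
  k <- switch(as.character(order),
    "0" = g / sum(g),
    "1" = (-x / sigma_mm^2) * g * h_mm,
    "2" = ((x^2 - sigma_mm^2) / sigma_mm^4) * g * h_mm,
    stop("order must be 0, 1 or 2")
  )
  if (order == 1L) k <- k - mean(k)          # exact zero response to constants
  if (order == 2L) k <- k - mean(k)
  k
}

# Kernel matrix for 1-D convolution with replicated (clamped) borders.
conv_matrix <- function(k, n) {
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (t in -r:r) {
    j <- clamp(seq_len(n) + t, 1L, n)
    K[cbind(seq_len(n), j)] <- K[cbind(seq_len(n), j)] + k[t + r + 1L]
  }
  K
}

# Convolve a 3D array along one axis with kernel k (clamped borders).
conv_axis <- function(arr, k, axis) {
  d <- dim(arr)
  K <- conv_matrix(k, d[axis])
  if (axis == 1L) {
    out <- K %*% matrix(arr, d[1], d[2] * d[3])
  } else if (axis == 2L) {
    m <- matrix(aperm(arr, c(2, 1, 3)), d[2], d[1] * d[3])
    out <- aperm(array(K %*% m, c(d[2], d[1], d[3])), c(2, 1, 3))
    return(out)
  } else {
    m <- matrix(aperm(arr, c(3, 1, 2)), d[3], d[1] * d[2])
    out <- aperm(array(K %*% m, c(d[3], d[1], d[2])), c(2, 3, 1))
    return(out)
  }
  array(out, d)
}

# Gaussian smoothing at a physical scale (mm) on an anisotropic grid.
smooth_gaussian <- function(arr, spacing, sigma_mm) {
  for (a in 1:3) arr <- conv_axis(arr, gauss_kernel(sigma_mm, spacing[a], 0L) /
                                    1, a)
  arr
}

# First derivatives (HU/mm) of the Gaussian-smoothed image.
gradient_fields <- function(arr, spacing, sigma_mm) {
  deriv <- function(orders) {
    out <- arr
    for (a in 1:3) out <- conv_axis(out, gauss_kernel(sigma_mm, spacing[a], orders[a]), a)
    out
  }
  list(gx = deriv(c(1, 0, 0)), gy = deriv(c(0, 1, 0)), gz = deriv(c(0, 0, 1)))
}

# The six independent second derivatives (HU/mm^2) at scale sigma_mm.
hessian_fields <- function(arr, spacing, sigma_mm) {
  if (sigma_mm < max(spacing))
    stop("analysis scale must be at least one voxel (", max(spacing), " mm)")
  deriv <- function(orders) {
    out <- arr
    for (a in 1:3) out <- conv_axis(out, gauss_kernel(sigma_mm, spacing[a], orders[a]), a)
    out
  }
  list(
    xx = deriv(c(2, 0, 0)), yy = deriv(c(0, 2, 0)), zz = deriv(c(0, 0, 2)),
    xy = deriv(c(1, 1, 0)), xz = deriv(c(1, 0, 1)), yz = deriv(c(0, 1, 1))
  )
}

# Vectorised eigenvalues of fields of symmetric 3x3 matrices, sorted by
# decreasing magnitude (|l1| >= |l2| >= |l3|). Uses the trigonometric
# closed form; inputs and outputs are arrays of identical shape.
symm3_eigenvalues <- function(H) {
  a11 <- H$xx; a22 <- H$yy; a33 <- H$zz
  a12 <- H$xy; a13 <- H$xz; a23 <- H$yz
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  safe_p <- ifelse(p > 0, p, 1)
  b11 <- (a11 - q) / safe_p; b22 <- (a22 - q) / safe_p; b33 <- (a33 - q) / safe_p
  b12 <- a12 / safe_p; b13 <- a13 / safe_p; b23 <- a23 / safe_p
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- clamp(detB / 2, -1, 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  zerop <- p2 <= 0
  if (any(zerop)) { e1[zerop] <- q[zerop]; e2[zerop] <- q[zerop]; e3[zerop] <- q[zerop] }
  # sort the algebraically-ordered triple (e1 >= e2 >= e3) by |.|
  big1 <- abs(e1) >= abs(e3)
  l1 <- ifelse(big1, e1, e3)
  rest <- ifelse(big1, e3, e1)
  big2 <- abs(e2) >= abs(rest)
  list(l1 = l1,
       l2 = ifelse(big2, e2, rest),
       l3 = ifelse(big2, rest, e2))
}

# Unit eigenvector field for a given eigenvalue field of symmetric 3x3
# matrices: cross products of the rows of (A - lambda I), picking the most
# numerically stable pair per voxel.
symm3_eigenvector <- function(H, lambda) {
  r1 <- list(H$xx - lambda, H$xy, H$xz)
  r2 <- list(H$xy, H$yy - lambda, H$yz)
  r3 <- list(H$xz, H$yz, H$zz - lambda)
  cross <- function(a, b) list(
    a[[2]] * b[[3]] - a[[3]] * b[[2]],
    a[[3]] * b[[1]] - a[[1]] * b[[3]],
    a[[1]] * b[[2]] - a[[2]] * b[[1]]
  )
  c1 <- cross(r1, r2); c2 <- cross(r1, r3); c3 <- cross(r2, r3)
  n1 <- c1[[1]]^2 + c1[[2]]^2 + c1[[3]]^2
  n2 <- c2[[1]]^2 + c2[[2]]^2 + c2[[3]]^2
  n3 <- c3[[1]]^2 + c3[[2]]^2 + c3[[3]]^2
  pick12 <- n1 >= n2
  vx <- ifelse(pick12, c1[[1]], c2[[1]])
  vy <- ifelse(pick12, c1[[2]], c2[[2]])
  vz <- ifelse(pick12, c1[[3]], c2[[3]])
  nb <- ifelse(pick12, n1, n2)
  use3 <- n3 > nb
  vx[use3] <- c3[[1]][use3]; vy[use3] <- c3[[2]][use3]; vz[use3] <- c3[[3]][use3]
  nn <- sqrt(vx^2 + vy^2 + vz^2)
  nn[nn == 0] <- 1
  list(x = vx / nn, y = vy / nn, z = vz / nn)
}
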