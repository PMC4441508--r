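#' In-memory CT volume
#'
#' A `ct_volume` is the canonical container used by every stage of the
#' pipeline: a 3D numeric array of Hounsfield Units together with the voxel
#' spacing and world origin. The third array axis is always the craniocaudal
#' (z) axis, increasing caudally-to-cranially; loaders reorder slices so this
#' holds. World coordinates are millimetres; the voxel with (1-based) index
#' `(i, j, k)` is centred at `origin + (c(i, j, k) - 0.5) * spacing`, so slice
#' `k` spans the half-open interval `[(k-1)*dz, k*dz)` relative to the origin.
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing numeric length-3, mm per voxel along each axis (> 0).
#' @param origin numeric length-3, world position (mm) of the volume corner.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers (mm/voxel)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers (mm)")
  if (any(!is.finite(voxels)))
    stop("voxels must be finite HU values")
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin,
         axial_axis = 3L),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f], origin (%.1f, %.1f, %.1f) mm\n",
              min(x$voxels), max(x$voxels),
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' World coordinates of voxel centres along one axis
#' @param vol a `ct_volume`
#' @param axis axis index 1..3
#' @return numeric vector of mm positions (voxel centres).
#' @export
axis_coords <- function(vol, axis) {
  d <- dim(vol$voxels)[axis]
  vol$origin[axis] + (seq_len(d) - 0.5) * vol$spacing[axis]
}

#' Convert between voxel indices and world millimetres
#'
#' `index_to_world` maps (possibly fractional) 1-based voxel indices to mm;
#' `world_to_index` is its inverse. Both accept a vector (one point) or an
#' n x 3 matrix.
#' @param vol a `ct_volume`
#' @param idx,pos length-3 vector or n x 3 matrix
#' @return same shape as the input
#' @export
index_to_world <- function(vol, idx) {
  if (is.null(dim(idx))) return(vol$origin + (as.numeric(idx) - 0.5) * vol$spacing)
  sweep(sweep(idx - 0.5, 2, vol$spacing, `*`), 2, vol$origin, `+`)
}

#' @rdname index_to_world
#' @export
world_to_index <- function(vol, pos) {
  if (is.null(dim(pos))) return((as.numeric(pos) - vol$origin) / vol$spacing + 0.5)
  sweep(sweep(pos, 2, vol$origin, `-`), 2, vol$spacing, `/`) + 0.5
}

# clamp a continuous index into the valid 1..d range
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# nearest valid voxel index for a world point; NULL if far outside
nearest_voxel <- function(vol, pos) {
  idx <- round(world_to_index(vol, pos))
  d <- dim(vol$voxels)
  as.integer(clamp(idx, 1, d))
}
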