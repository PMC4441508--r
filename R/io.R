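# Volume readers and writers.
#
# Three on-disk forms are supported: NIfTI (.nii/.nii.gz, via RNifti),
# MetaImage (.mhd/.mha) and single-frame CT DICOM series (one file per
# slice, explicit-VR little-endian; see dicom.R). All loaders return the
# canonical `ct_volume`: HU with rescale applied, axis 3 craniocaudal with
# slices sorted by position.

#' Load a CT volume
#'
#' Reads a DICOM series directory, a NIfTI file or a MetaImage file into a
#' [ct_volume()]. Slices of a DICOM series are sorted by their position tag
#' (never by file name), the rescale slope/intercept is applied so voxels
#' are in HU, and inter-slice gaps are checked for consistency.
#'
#' @param path a directory containing a DICOM series, or a `.nii`,
#'   `.nii.gz`, `.mhd` or `.mha` file.
#' @return a [ct_volume()].
#' @export
load_volume <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (!file.exists(path)) stop("no such file or directory: ", path)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) return(read_nifti_volume(path))
  if (grepl("\\.(mhd|mha)$", lower)) return(read_metaimage(path))
  stop("unrecognised volume format: ", path,
       " (expected DICOM directory, .nii[.gz], .mhd or .mha)")
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3 || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    stop("NIfTI header of ", path, " lacks valid voxel spacing")
  vox <- array(as.numeric(img), dim(img)[1:3])
  ct_volume(vox, spacing = pd[1:3], origin = c(0, 0, 0))
}

#' Write a volume as NIfTI
#'
#' Voxels are stored as float64 so phantom round trips are bit-identical;
#' the voxel spacing is recorded in the header.
#'
#' @param vol a [ct_volume()]
#' @param path output `.nii` or `.nii.gz` path
#' @export
write_nifti_volume <- function(vol, path) {
  arr <- structure(vol$voxels, pixdim = vol$spacing)
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

# --- MetaImage (.mhd + .raw, or single-file .mha) ---------------------------

metaio_types <- c(MET_SHORT = "integer", MET_USHORT = "integer",
                  MET_FLOAT = "numeric", MET_DOUBLE = "numeric",
                  MET_UCHAR = "integer", MET_CHAR = "integer",
                  MET_INT = "integer")
metaio_sizes <- c(MET_SHORT = 2L, MET_USHORT = 2L, MET_FLOAT = 4L,
                  MET_DOUBLE = 8L, MET_UCHAR = 1L, MET_CHAR = 1L, MET_INT = 4L)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) break
    hdr <- c(hdr, line)
    if (grepl("^ElementDataFile", line)) break
  }
  kv <- strsplit(hdr, "\\s*=\\s*")
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = "="), character(1))
  h <- stats::setNames(trimws(vals), trimws(keys))
  need <- function(k) {
    if (is.na(h[k])) stop("MetaImage header of ", path, " is missing ", k)
    h[[k]]
  }
  dims <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
  spacing_key <- if (!is.na(h["ElementSpacing"])) "ElementSpacing" else "ElementSize"
  if (is.na(h[spacing_key]))
    stop("MetaImage header of ", path, " is missing ElementSpacing")
  spacing <- as.numeric(strsplit(h[[spacing_key]], "\\s+")[[1]])
  etype <- need("ElementType")
  if (!etype %in% names(metaio_types))
    stop("unsupported MetaImage ElementType: ", etype)
  datafile <- need("ElementDataFile")
  n <- prod(dims)
  if (identical(datafile, "LOCAL")) {
    raw <- readBin(con, metaio_types[[etype]], n = n,
                   size = metaio_sizes[[etype]], endian = "little",
                   signed = !etype %in% c("MET_UCHAR", "MET_USHORT"))
  } else {
    rawpath <- file.path(dirname(path), datafile)
    rcon <- file(rawpath, "rb")
    on.exit(close(rcon), add = TRUE)
    raw <- readBin(rcon, metaio_types[[etype]], n = n,
                   size = metaio_sizes[[etype]], endian = "little",
                   signed = !etype %in% c("MET_UCHAR", "MET_USHORT"))
  }
  if (length(raw) != n) stop("MetaImage pixel data of ", path, " is truncated")
  vox <- array(as.numeric(raw), dims)
  origin <- if (!is.na(h["Offset"]))
    as.numeric(strsplit(h[["Offset"]], "\\s+")[[1]]) else c(0, 0, 0)
  ct_volume(vox, spacing = spacing, origin = origin)
}

#' Write a volume as MetaImage
#'
#' Single-file `.mha` with float64 voxels (bit-identical round trip) or a
#' `.mhd` header plus `.raw` pixel file.
#'
#' @param vol a [ct_volume()]
#' @param path output `.mha` or `.mhd` path
#' @export
write_metaimage <- function(vol, path) {
  d <- dim(vol$voxels)
  single <- grepl("\\.mha$", tolower(path))
  datafile <- if (single) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path),
                                                 ignore.case = TRUE), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste("DimSize =", paste(d, collapse = " ")),
    paste("ElementSpacing =", paste(format(vol$spacing, digits = 17), collapse = " ")),
    paste("Offset =", paste(format(vol$origin, digits = 17), collapse = " ")),
    "ElementType = MET_DOUBLE",
    paste("ElementDataFile =", datafile)
  )
  con <- file(path, "wb")
  writeLines(hdr, con)
  if (single) {
    writeBin(as.numeric(vol$voxels), con, size = 8, endian = "little")
    close(con)
  } else {
    close(con)
    rcon <- file(file.path(dirname(path), datafile), "wb")
    writeBin(as.numeric(vol$voxels), rcon, size = 8, endian = "little")
    close(rcon)
  }
  invisible(path)
}
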