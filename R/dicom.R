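# Minimal single-frame CT DICOM series support.
#
# Scope: uncompressed explicit-VR little-endian files, one axial slice per
# file, with the tags a CT pipeline needs (pixel geometry, slice position,
# rescale slope/intercept, signed 16-bit pixel data). This covers the
# series the package itself writes plus typical exported CT slices; it is
# not a general DICOM toolkit.

uid_root <- "1.2.826.0.1.3680043.10.1457"

dcm_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")

dcm_string <- function(s, pad = charToRaw(" ")) {
  b <- charToRaw(s)
  if (length(b) %% 2 == 1) b <- c(b, pad)
  b
}

# one explicit-VR element as a raw vector
dcm_element <- function(group, elem, vr, value) {
  if (is.character(value))
    value <- dcm_string(value, if (vr == "UI") as.raw(0) else charToRaw(" "))
  hdr <- c(dcm_uint16(group), dcm_uint16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, as.raw(c(0, 0)), writeBin(length(value), raw(), size = 4, endian = "little"),
      value)
  } else {
    c(hdr, dcm_uint16(length(value)), value)
  }
}

#' Write a volume as a single-frame CT DICOM series
#'
#' One explicit-VR little-endian file per axial slice, carrying pixel
#' spacing, slice position, slice thickness and a rescale transform
#' (slope 1, intercept -1024). Pixels are stored as signed 16-bit integers,
#' so HU values are rounded to the nearest integer on write.
#'
#' @param vol a [ct_volume()]
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @return invisibly, the written file paths
#' @export
write_dicom_series <- function(vol, dir, prefix = "slice") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(vol$voxels)
  sp <- vol$spacing
  intercept <- -1024
  series_uid <- paste0(uid_root, ".1.1")
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    ipp <- vol$origin + sp * 0.5 + c(0, 0, (k - 1) * sp[3])
    stored <- as.integer(round(vol$voxels[, , k])) - as.integer(intercept)
    pix <- writeBin(stored, raw(), size = 2, endian = "little")
    meta_body <- c(
      dcm_element(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      dcm_element(0x0002, 0x0003, "UI", paste0(series_uid, ".", k)),
      dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
    )
    ds <- c(
      dcm_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      dcm_element(0x0008, 0x0018, "UI", paste0(series_uid, ".", k)),
      dcm_element(0x0008, 0x0060, "CS", "CT"),
      dcm_element(0x0018, 0x0050, "DS", format(sp[3])),
      dcm_element(0x0020, 0x000E, "UI", series_uid),
      dcm_element(0x0020, 0x0013, "IS", format(k)),
      dcm_element(0x0020, 0x0032, "DS",
                  paste(format(ipp, digits = 12), collapse = "\\")),
      dcm_element(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      dcm_element(0x0028, 0x0002, "US", dcm_uint16(1)),
      dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_element(0x0028, 0x0010, "US", dcm_uint16(d[2])),  # Rows (y)
      dcm_element(0x0028, 0x0011, "US", dcm_uint16(d[1])),  # Columns (x)
      dcm_element(0x0028, 0x0030, "DS",
                  paste(format(c(sp[2], sp[1]), digits = 12), collapse = "\\")),
      dcm_element(0x0028, 0x0100, "US", dcm_uint16(16)),
      dcm_element(0x0028, 0x0101, "US", dcm_uint16(16)),
      dcm_element(0x0028, 0x0102, "US", dcm_uint16(15)),
      dcm_element(0x0028, 0x0103, "US", dcm_uint16(1)),
      dcm_element(0x0028, 0x1052, "DS", format(intercept)),
      dcm_element(0x0028, 0x1053, "DS", "1"),
      dcm_element(0x7FE0, 0x0010, "OW", pix)
    )
    meta <- c(dcm_element(0x0002, 0x0000, "UL",
                          writeBin(length(meta_body), raw(), size = 4,
                                   endian = "little")),
              meta_body)
    path <- file.path(dir, sprintf("%s_%04d.dcm", prefix, k))
    con <- file(path, "wb")
    writeBin(raw(128), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(c(meta, ds), con)
    close(con)
    paths[k] <- path
  }
  invisible(paths)
}

# parse one explicit-VR little-endian file into a named list of raw values
dcm_parse_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop(path, " is not a DICOM part-10 file")
  pos <- 133L
  n <- length(raw)
  out <- list()
  u16 <- function(at) readBin(raw[at:(at + 1L)], "integer", size = 2,
                              signed = FALSE, endian = "little")
  u32 <- function(at) readBin(raw[at:(at + 3L)], "integer", size = 4,
                              endian = "little")
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop(path, ": implicit-VR or non-conformant element at byte ", pos,
           " (only explicit-VR little-endian is supported)")
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    if (len < 0 || vstart + len - 1L > n)
      stop(path, ": truncated DICOM element ",
           sprintf("(%04x,%04x)", group, elem))
    key <- sprintf("%04x%04x", group, elem)
    out[[key]] <- list(vr = vr, value = if (len > 0)
      raw[vstart:(vstart + len - 1L)] else raw(0))
    pos <- vstart + len
  }
  out
}

dcm_str_value <- function(el) trimws(rawToChar(el$value[el$value != as.raw(0)]))
dcm_num_values <- function(el) as.numeric(strsplit(dcm_str_value(el), "\\\\")[[1]])
dcm_us_value <- function(el) readBin(el$value, "integer", size = 2,
                                     signed = FALSE, endian = "little")

dcm_need <- function(ds, key, what, path) {
  if (is.null(ds[[key]]))
    stop("DICOM file ", path, " is missing required tag ", what)
  ds[[key]]
}

#' Read a single-frame CT DICOM series
#'
#' Reads every DICOM file in `dir`, sorts slices craniocaudally by the
#' slice-position tag (file names are ignored for ordering), applies the
#' rescale slope/intercept, and validates inter-slice spacing: gaps that
#' deviate from the median by more than 10 percent abort with the offending
#' slice named.
#'
#' @param dir directory of per-slice DICOM files
#' @return a [ct_volume()]
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no DICOM files found in ", dir)
  slices <- lapply(files, function(f) {
    ds <- dcm_parse_file(f)
    ts <- ds[["00020010"]]
    if (!is.null(ts) && dcm_str_value(ts) != "1.2.840.10008.1.2.1")
      stop(f, ": unsupported transfer syntax ", dcm_str_value(ts))
    ipp <- dcm_num_values(dcm_need(ds, "00200032", "ImagePositionPatient", f))
    psp <- dcm_num_values(dcm_need(ds, "00280030", "PixelSpacing", f))
    rows <- dcm_us_value(dcm_need(ds, "00280010", "Rows", f))
    cols <- dcm_us_value(dcm_need(ds, "00280011", "Columns", f))
    bits <- dcm_us_value(dcm_need(ds, "00280100", "BitsAllocated", f))
    if (bits != 16) stop(f, ": only 16-bit pixel data is supported")
    signed <- !is.null(ds[["00280103"]]) && dcm_us_value(ds[["00280103"]]) == 1
    slope <- if (!is.null(ds[["00281053"]])) dcm_num_values(ds[["00281053"]]) else 1
    intercept <- if (!is.null(ds[["00281052"]])) dcm_num_values(ds[["00281052"]]) else 0
    pix <- dcm_need(ds, "7fe00010", "PixelData", f)
    vals <- readBin(pix$value, "integer", n = rows * cols, size = 2,
                    signed = signed, endian = "little")
    if (length(vals) != rows * cols) stop(f, ": truncated pixel data")
    list(file = f, z = ipp[3], ipp = ipp, dy = psp[1], dx = psp[2],
         rows = rows, cols = cols,
         hu = matrix(vals * slope + intercept, nrow = cols, ncol = rows))
  })
  ord <- order(vapply(slices, `[[`, numeric(1), "z"))
  slices <- slices[ord]
  dx <- vapply(slices, `[[`, numeric(1), "dx")
  dy <- vapply(slices, `[[`, numeric(1), "dy")
  rows <- vapply(slices, `[[`, numeric(1), "rows")
  cols <- vapply(slices, `[[`, numeric(1), "cols")
  if (length(unique(rows)) > 1 || length(unique(cols)) > 1 ||
      diff(range(dx)) > 1e-6 || diff(range(dy)) > 1e-6)
    stop("DICOM series in ", dir, " has inconsistent in-plane geometry")
  zs <- vapply(slices, `[[`, numeric(1), "z")
  if (length(zs) < 2) stop("DICOM series in ", dir, " has fewer than 2 slices")
  gaps <- diff(zs)
  med <- stats::median(gaps)
  if (med <= 0) stop("DICOM series in ", dir, " has non-increasing slice positions")
  bad <- which(abs(gaps - med) > 0.1 * med)
  if (length(bad))
    stop("inconsistent inter-slice gap at slice ",
         basename(slices[[bad[1] + 1]]$file),
         sprintf(" (gap %.3f mm vs median %.3f mm)", gaps[bad[1]], med))
  vox <- array(0, c(cols[1], rows[1], length(slices)))
  for (k in seq_along(slices)) vox[, , k] <- slices[[k]]$hu
  origin <- slices[[1]]$ipp - c(dx[1], dy[1], med) * 0.5
  ct_volume(vox, spacing = c(dx[1], dy[1], med), origin = origin)
}
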