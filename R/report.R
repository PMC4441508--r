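# Case reports: structured JSON plus caliper overlay images.

caliper_to_list <- function(cal, vol) {
  if (is.null(cal)) return(NULL)
  list(
    slice_index = cal$slice_index,
    length_mm = cal$length_mm,
    endpoints_mm = lapply(1:2, function(r) as.numeric(cal$endpoints[r, ])),
    endpoints_voxel = lapply(1:2, function(r)
      as.numeric(world_to_index(vol, cal$endpoints[r, ])))
  )
}

#' Write a case report
#'
#' Emits `report.json` (ratio, flags, caliper endpoints in mm and voxel
#' coordinates, septum plane, per-stage runtimes) and one PNG overlay per
#' caliper showing the corresponding axial slice with the caliper drawn.
#' A flagged case without a ratio omits the ratio field.
#'
#' @param report a `case_report` from [run_case()].
#' @param volume the analysed [ct_volume()].
#' @param dir output directory (created if needed).
#' @return invisibly, the path of the JSON file.
#' @export
write_report <- function(report, volume, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- list(
    flags = as.list(report$flags),
    rv_caliper = caliper_to_list(report$rv_caliper, volume),
    lv_caliper = caliper_to_list(report$lv_caliper, volume),
    septum = report$septum_summary,
    mean_hu = report$mean_hu,
    timings_s = report$timings_s
  )
  if (!is.null(report$ratio)) out$ratio <- report$ratio
  path <- file.path(dir, "report.json")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  for (ch in c("rv", "lv")) {
    cal <- report[[paste0(ch, "_caliper")]]
    if (is.null(cal)) next
    png_path <- file.path(dir, paste0(ch, "_caliper.png"))
    write_caliper_overlay(volume, cal, png_path)
  }
  invisible(path)
}

#' Read a case report written by [write_report()]
#' @param path the `report.json` path (or its directory).
#' @return the parsed report structure.
#' @export
read_report <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "report.json")
  jsonlite::read_json(path, simplifyVector = FALSE)
}

# axial slice as an RGB overlay with the caliper drawn in red
write_caliper_overlay <- function(vol, cal, path, window = c(-150, 450)) {
  k <- cal$slice_index
  sl <- vol$voxels[, , k]
  gray <- clamp((sl - window[1]) / diff(window), 0, 1)
  # image rows = y, columns = x for conventional display
  img <- array(t(gray), c(ncol(sl), nrow(sl), 3))
  e <- rbind(world_to_index(vol, cal$endpoints[1, ]),
             world_to_index(vol, cal$endpoints[2, ]))
  nsteps <- max(2L, ceiling(2 * max(abs(e[2, 1:2] - e[1, 1:2]))))
  ts <- seq(0, 1, length.out = nsteps)
  xi <- round(e[1, 1] + ts * (e[2, 1] - e[1, 1]))
  yi <- round(e[1, 2] + ts * (e[2, 2] - e[1, 2]))
  okp <- xi >= 1 & xi <= nrow(sl) & yi >= 1 & yi <= ncol(sl)
  img[cbind(yi[okp], xi[okp], 1)] <- 1
  img[cbind(yi[okp], xi[okp], 2)] <- 0
  img[cbind(yi[okp], xi[okp], 3)] <- 0
  png::writePNG(img, path)
  invisible(path)
}
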