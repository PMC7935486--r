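#' Read / write timed image stacks as TIFF with a JSON sidecar
#'
#' Stacks are written as multi-page 32-bit float TIFF; the physical
#' calibration (`pixel_size_um`, `frame_interval_min`) travels in a JSON
#' sidecar next to the image file.
#'
#' @param stack a `channel_stack`.
#' @param path output TIFF path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  d <- dim(stack$frames)
  rng <- range(stack$frames)
  scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  pages <- lapply(seq_len(d[3]),
                  function(k) (stack$frames[, , k] - rng[1]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(pixel_size_um = stack$pixel_size,
                            frame_interval_min = stack$frame_interval,
                            intensity_offset = rng[1],
                            intensity_scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @describeIn write_stack Read a stack written by [write_stack()] (or any
#'   grayscale multi-page TIFF plus sidecar).
#' @param path TIFF path with `<path>.json` sidecar.
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  if (!file.exists(side)) stopf("sidecar '%s' not found", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (key in c("pixel_size_um", "frame_interval_min"))
    if (is.null(meta[[key]]))
      stopf("sidecar '%s' lacks required key '%s'", side, key)
  offset <- meta$intensity_offset %||% 0
  scale <- meta$intensity_scale %||% 1
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * scale + offset
  channel_stack(arr, meta$pixel_size_um, meta$frame_interval_min)
}

#' Write a kymograph as CSV (and optionally TIFF)
#'
#' @param kymo a `kymograph`.
#' @param csv_path CSV output (rows = positions with `s_um` column).
#' @param tiff_path optional float TIFF output.
#' @return `csv_path`, invisibly.
#' @export
write_kymograph <- function(kymo, csv_path, tiff_path = NULL) {
  stopifnot(inherits(kymo, "kymograph"))
  df <- data.frame(s_um = attr(kymo, "s"), unclass(kymo))
  names(df)[-1] <- sprintf("t_%g", attr(kymo, "t"))
  write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(tiff_path)) {
    m <- unclass(kymo)
    m[is.na(m)] <- 0
    rng <- range(m)
    if (rng[2] > rng[1]) m <- (m - rng[1]) / (rng[2] - rng[1])
    tiff::writeTIFF(m, tiff_path, bits.per.sample = 32L)
  }
  invisible(csv_path)
}

#' Read a traced polyline from CSV
#'
#' Expects two columns (`row`, `col` in px, or `x`, `y` in um, in that
#' order); returns the coordinate matrix.
#'
#' @param path CSV path.
#' @return Two-column numeric matrix.
#' @export
read_polyline_csv <- function(path) {
  df <- read.csv(path)
  if (ncol(df) < 2) stopf("'%s' must have two coordinate columns", path)
  check_matrix2(df[, 1:2], path)
}
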