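# File interfaces: long-format CSVs for curves/tracks/lanes/series with
# sidecar JSON ground-truth records, and multi-page TIFF for image stacks
# with pixel size recorded in a sidecar JSON (no reliance on TIFF tag
# dialects).

#' Write a generated dataset with its ground-truth sidecar
#'
#' Writes the tabular part as CSV and the `sim_truth` record as
#' `<path>.truth.json`.
#'
#' @param data Data frame to write.
#' @param truth A `sim_truth` object (or NULL to skip).
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_with_truth <- function(data, truth, path) {
  utils::write.csv(data, path, row.names = FALSE)
  if (!is.null(truth)) {
    tr <- unclass(truth)
    tr$params <- lapply(tr$params, function(p) {
      if (is.data.frame(p)) as.list(p)
      else if (is.atomic(p) && !is.null(names(p))) as.list(p)
      else p
    })
    jsonlite::write_json(tr, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a long-format melt-curve table
#' @param path CSV with columns `curve_id`, `label`, `temp_C`, `fluor`.
#' @return Data frame.
#' @export
read_melt_curves <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("curve_id", "label", "temp_C", "fluor")
  if (!all(need %in% names(x)))
    stopf("melt-curve CSV needs columns: %s", paste(need, collapse = ", "))
  x
}

#' Read a fiber track table
#' @param path CSV with columns `track_id`, `order`, `idu_len_um`,
#'   `cldu_len_um` (optional `ssdna_ok`).
#' @return Data frame.
#' @export
read_fiber_tracks <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "order", "idu_len_um", "cldu_len_um")
  if (!all(need %in% names(x)))
    stopf("track CSV needs columns: %s", paste(need, collapse = ", "))
  x
}

#' Read gel lane profiles from long format
#' @param path CSV with columns `lane_id`, `position`, `intensity`.
#' @return Named list of [gel_lane()] objects.
#' @export
read_gel_lanes <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lane_id", "position", "intensity")
  if (!all(need %in% names(x)))
    stopf("lane CSV needs columns: %s", paste(need, collapse = ", "))
  lapply(split(x, x$lane_id), function(d) {
    d <- d[order(d$position), ]
    gel_lane(d$position, d$intensity, lane_meta = list(lane = d$lane_id[1]))
  })
}

#' Write an image stack as multi-page TIFF with a calibration sidecar
#'
#' Frames are rescaled to the 32-bit float TIFF range as-is; the pixel size
#' (and frame times, if given) go to `<path>.meta.json`.
#'
#' @param frames List of numeric matrices.
#' @param path TIFF output path.
#' @param pixel_size_um Pixel size, micrometres.
#' @param times_min Optional frame times.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(frames, path, pixel_size_um = NA,
                             times_min = NULL) {
  mx <- max(vapply(frames, max, 1))
  mn <- min(vapply(frames, min, 1))
  scale <- if (mx > mn) mx - mn else 1
  tiff::writeTIFF(lapply(frames, function(f) (f - mn) / scale), path,
                  bits.per.sample = 32L)
  jsonlite::write_json(list(pixel_size_um = pixel_size_um,
                            intensity_scale = scale, intensity_offset = mn,
                            times_min = times_min),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an image stack written by [write_stack_tiff()]
#' @param path TIFF path (expects the `.meta.json` sidecar).
#' @return List with `frames`, `pixel_size_um`, `times_min`.
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(frames, function(f)
    f * meta$intensity_scale + (meta$intensity_offset %||% 0))
  list(frames = frames, pixel_size_um = meta$pixel_size_um,
       times_min = meta$times_min)
}
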