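# Rule-based nucleus / chromocenter quantification: segmentation in the DAPI
# channel, geometry filters (roundness > 0.8, area 60-300 um^2, no border
# contact), intensity sums, expression binning, the DAPI-StDev decondensation
# proxy, Pearson colocalization and line profiles.

#' Construct a calibrated multi-channel image field
#'
#' @param channels Named list of numeric matrices, all the same size. A
#'   `DAPI` channel is required for segmentation.
#' @param pixel_size_um Pixel edge length in micrometres (> 0).
#' @return An `image_field` object.
#' @export
image_field <- function(channels, pixel_size_um) {
  stopifnot(is.list(channels), length(channels) >= 1L, !is.null(names(channels)))
  if (!all(vapply(channels, is.matrix, TRUE)))
    stopf("all channels must be matrices")
  dims <- lapply(channels, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stopf("all channels must have identical dimensions")
  assert_scalar_num(pixel_size_um, "pixel_size_um", lower = 0, strict = TRUE)
  structure(list(channels = channels, pixel_size_um = pixel_size_um),
            class = "image_field")
}

# chain-code perimeter of a single-object binary mask: length of the traced
# 8-connected contour polygon, with the standard 0.95 correction for smooth
# shapes (chain length overestimates a circle's circumference by ~5%)
mask_perimeter <- function(mask) {
  w <- which(mask, arr.ind = TRUE)   # crop to the object's bounding box
  r <- range(w[, 1]); c <- range(w[, 2])
  mask <- mask[max(1, r[1] - 1):min(nrow(mask), r[2] + 1),
               max(1, c[1] - 1):min(ncol(mask), c[2] + 1), drop = FALSE]
  oc <- EBImage::ocontour(EBImage::bwlabel(mask * 1))
  ctr <- oc[[1]]
  if (nrow(ctr) < 3L) return(4)          # degenerate blob: ~unit square
  poly <- rbind(ctr, ctr[1, , drop = FALSE])
  0.95 * sum(sqrt(rowSums(diff(poly)^2)))
}

#' Segment nuclei in the DAPI channel and apply the geometry filters
#'
#' Thresholds DAPI (Otsu by default), labels connected components and
#' measures, per nucleus: area (um^2), roundness `4*pi*A/P^2` (perimeter from
#' the traced contour, clipped at 1), border contact, and per-channel sum and
#' population-SD intensities. `passes_filters` is TRUE iff roundness >
#' `round_min`, area within `area_range` and the nucleus does not touch the
#' image border.
#'
#' @param field An [image_field()] with a `DAPI` channel.
#' @param threshold_method `"otsu"` or `"fixed"` (then give `threshold`).
#' @param threshold Fixed DAPI threshold, used when `threshold_method = "fixed"`.
#' @param min_area_px Components smaller than this many pixels are discarded
#'   as debris.
#' @param round_min Roundness filter lower bound.
#' @param area_range Nuclear-area filter `c(low, high)` in um^2.
#' @return List with `mask` (integer label matrix) and `nuclei` (one row per
#'   nucleus: `label_id`, `area_um2`, `roundness`, `touches_border`,
#'   `sum_<channel>`, `sd_<channel>`, `passes_filters`).
#' @export
segment_nuclei <- function(field, threshold_method = c("otsu", "fixed"),
                           threshold = NULL, min_area_px = 25,
                           round_min = 0.8, area_range = c(60, 300)) {
  stopifnot(inherits(field, "image_field"))
  if (!"DAPI" %in% names(field$channels)) stopf("DAPI channel is required")
  threshold_method <- match.arg(threshold_method)
  dapi <- field$channels$DAPI
  th <- if (threshold_method == "otsu") {
    rng <- range(dapi)
    if (diff(rng) == 0) stopf("DAPI channel is constant; cannot threshold")
    scaled <- (dapi - rng[1]) / diff(rng)
    rng[1] + diff(rng) * EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  } else {
    if (is.null(threshold)) stopf("threshold required for fixed method")
    threshold
  }
  bin <- dapi > th
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  labm <- EBImage::imageData(lab)
  nlab <- max(labm)
  if (nlab == 0L) {
    warning("empty segmentation: no nuclei found")
    return(list(mask = labm, nuclei = empty_nucleus_table(names(field$channels))))
  }
  psz <- field$pixel_size_um
  nr <- nrow(labm); nc <- ncol(labm)
  rows <- vector("list", nlab)
  keep_id <- 0L
  out_mask <- array(0L, dim(labm))
  for (id in seq_len(nlab)) {
    sel <- labm == id
    npx <- sum(sel)
    if (npx < min_area_px) next
    keep_id <- keep_id + 1L
    out_mask[sel] <- keep_id
    area <- npx * psz^2
    per <- mask_perimeter(sel) * psz
    roundness <- min(1, 4 * pi * area / per^2)
    w <- which(sel, arr.ind = TRUE)
    border <- any(w[, 1] == 1L | w[, 1] == nr | w[, 2] == 1L | w[, 2] == nc)
    rec <- data.frame(label_id = keep_id, area_um2 = area,
                      roundness = roundness, touches_border = border)
    for (ch in names(field$channels)) {
      px <- field$channels[[ch]][sel]
      rec[[paste0("sum_", ch)]] <- sum(px)
      rec[[paste0("sd_", ch)]] <- if (npx > 1L) pop_sd(px) else 0
    }
    rec$passes_filters <- roundness > round_min &&
      area >= area_range[1] && area <= area_range[2] && !border
    rows[[keep_id]] <- rec
  }
  nuclei <- if (keep_id > 0L) do.call(rbind, rows[seq_len(keep_id)])
            else empty_nucleus_table(names(field$channels))
  if (keep_id == 0L) warning("empty segmentation: no nuclei found")
  list(mask = out_mask, nuclei = nuclei)
}

empty_nucleus_table <- function(channel_names) {
  rec <- data.frame(label_id = integer(0), area_um2 = numeric(0),
                    roundness = numeric(0), touches_border = logical(0))
  for (ch in channel_names) {
    rec[[paste0("sum_", ch)]] <- numeric(0)
    rec[[paste0("sd_", ch)]] <- numeric(0)
  }
  rec$passes_filters <- logical(0)
  rec
}

#' Segment DAPI-bright chromocenters inside segmented nuclei
#'
#' Pixels above `spot_threshold` within each nucleus mask are connected-
#' labelled as pericentric heterochromatin spots; channel intensities are
#' summed under each spot mask. Spots outside every nucleus are never
#' reported. The default threshold is per-nucleus: mean + 2 SD of the
#' nuclear DAPI intensity.
#'
#' @param field An [image_field()].
#' @param nuclei_mask Integer label matrix from [segment_nuclei()].
#' @param spot_threshold Absolute DAPI threshold; `NULL` for the per-nucleus
#'   default.
#' @return Data frame: `label_id`, `parent_nucleus`, `area_px`,
#'   `sum_<channel>` columns.
#' @export
segment_chromocenters <- function(field, nuclei_mask, spot_threshold = NULL) {
  stopifnot(inherits(field, "image_field"))
  dapi <- field$channels$DAPI
  ids <- setdiff(sort(unique(as.integer(nuclei_mask))), 0L)
  rows <- list()
  spot_id <- 0L
  for (nid in ids) {
    sel <- nuclei_mask == nid
    px <- dapi[sel]
    th <- spot_threshold %||% (mean(px) + 2 * pop_sd(px))
    spot_bin <- array(FALSE, dim(dapi))
    spot_bin[sel] <- dapi[sel] > th
    if (!any(spot_bin)) next
    if (sum(spot_bin) > 0.5 * sum(sel))
      warning(sprintf("chromocenter mask covers > 50%% of nucleus %d", nid))
    slab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(spot_bin * 1)))
    for (sid in seq_len(max(slab))) {
      ssel <- slab == sid
      spot_id <- spot_id + 1L
      rec <- data.frame(label_id = spot_id, parent_nucleus = nid,
                        area_px = sum(ssel))
      for (ch in names(field$channels))
        rec[[paste0("sum_", ch)]] <- sum(field$channels[[ch]][ssel])
      rows[[spot_id]] <- rec
    }
  }
  if (!length(rows)) {
    rec <- data.frame(label_id = integer(0), parent_nucleus = integer(0),
                      area_px = integer(0))
    for (ch in names(field$channels)) rec[[paste0("sum_", ch)]] <- numeric(0)
    return(rec)
  }
  do.call(rbind, rows)
}

#' Normalize per-nucleus intensities to a control population
#'
#' Each record's channel sum intensity is divided by the control group's
#' median (or another location statistic), mirroring plotting "as a ratio to
#' the values of the respective control cells".
#'
#' @param records Nucleus table with a `sum_<channel>` column.
#' @param channel Channel name.
#' @param control_records Control nucleus table (non-empty).
#' @param stat Normalization statistic: `"median"` (default) or `"mean"`.
#' @return `records` with an added `norm_<channel>` column.
#' @export
measure_and_normalize <- function(records, channel, control_records,
                                  stat = c("median", "mean")) {
  stat <- match.arg(stat)
  col <- paste0("sum_", channel)
  if (!col %in% names(records) || !col %in% names(control_records))
    stopf("channel `%s` not measured", channel)
  if (nrow(control_records) == 0L) stopf("control set is empty")
  ref <- if (stat == "median") stats::median(control_records[[col]])
         else mean(control_records[[col]])
  if (ref == 0) stopf("control %s is zero; cannot normalize", stat)
  records[[paste0("norm_", channel)]] <- records[[col]] / ref
  records
}

#' Default expression-group bins
#'
#' Half-open intensity bins (lower bound inclusive) used to stratify cells by
#' expression level of the tagged construct: low-expression subgroups a/b/c
#' below 1000 a.u. and high-expression groups 2/3/4 above, the top group
#' open-ended.
#'
#' @return Data frame: `name`, `low`, `high`.
#' @export
default_expression_bins <- function() {
  data.frame(name = c("a", "b", "c", "2", "3", "4"),
             low = c(0, 100, 500, 1000, 2000, 3000),
             high = c(100, 500, 1000, 2000, 3000, Inf),
             stringsAsFactors = FALSE)
}

#' Annotate records with expression groups
#'
#' Assigns each record's channel sum intensity to a half-open bin
#' `[low, high)`; intensities at or above the top bound fall into the
#' open-ended top group, intensities below the lowest bound are `"unbinned"`.
#'
#' @param records Nucleus table with a `sum_<channel>` column.
#' @param channel Channel name.
#' @param bins Bin table as from [default_expression_bins()].
#' @return `records` with an `expression_group` column.
#' @export
bin_by_expression <- function(records, channel,
                              bins = default_expression_bins()) {
  stopifnot(all(c("name", "low", "high") %in% names(bins)))
  if (is.unsorted(bins$low) || any(bins$high[-nrow(bins)] != bins$low[-1]))
    stopf("bins must be ordered, disjoint and contiguous")
  col <- paste0("sum_", channel)
  if (!col %in% names(records)) stopf("channel `%s` not measured", channel)
  x <- records[[col]]
  grp <- rep("unbinned", length(x))
  for (i in seq_len(nrow(bins)))
    grp[x >= bins$low[i] & x < bins$high[i]] <- bins$name[i]
  records$expression_group <- grp
  records
}

#' DAPI standard deviation as a chromatin decondensation proxy
#'
#' Population SD of per-pixel intensity within a nuclear mask; condensed
#' chromatin (bright chromocenters on a dimmer nucleoplasm) gives high
#' values, globally decondensed (flattened) DAPI gives low values.
#'
#' @param field An [image_field()].
#' @param mask Logical or 0/1 matrix selecting one nucleus.
#' @param channel Channel name (default `"DAPI"`).
#' @return The population standard deviation (a.u.).
#' @export
decondensation_index <- function(field, mask, channel = "DAPI") {
  stopifnot(inherits(field, "image_field"))
  sel <- mask > 0
  if (sum(sel) < 2L) stopf("mask must contain >= 2 pixels")
  pop_sd(field$channels[[channel]][sel])
}

#' Pearson colocalization between two channels under a mask
#'
#' @param field An [image_field()].
#' @param channel_a,channel_b Channel names.
#' @param mask Logical or 0/1 matrix with >= 10 selected pixels.
#' @return Pearson correlation coefficient of the masked pixel pairs.
#' @export
pearson_coloc <- function(field, channel_a, channel_b, mask) {
  stopifnot(inherits(field, "image_field"))
  sel <- mask > 0
  if (sum(sel) < 10L) stopf("mask must contain >= 10 pixels")
  a <- field$channels[[channel_a]][sel]
  b <- field$channels[[channel_b]][sel]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stopf("constant channel under mask; correlation undefined")
  stats::cor(a, b)
}

#' Intensity line profile along a segment
#'
#' Bilinear-interpolated intensities sampled at unit-pixel spacing along the
#' segment from `start_point` to `end_point` (both `c(row, col)`, inside the
#' field); distances are reported in micrometres.
#'
#' @param field An [image_field()].
#' @param start_point,end_point Numeric `c(row, col)` endpoints.
#' @param channels Channel names to sample (default: all).
#' @return Data frame: `distance_um` plus one column per channel.
#' @export
line_profile <- function(field, start_point, end_point,
                         channels = names(field$channels)) {
  stopifnot(inherits(field, "image_field"))
  dm <- dim(field$channels[[1]])
  pts <- rbind(start_point, end_point)
  if (any(pts[, 1] < 1 | pts[, 1] > dm[1] | pts[, 2] < 1 | pts[, 2] > dm[2]))
    stopf("endpoints must lie inside the field")
  len <- sqrt(sum((end_point - start_point)^2))
  if (len == 0) stopf("zero-length segment")
  n <- ceiling(len) + 1L
  tt <- seq(0, 1, length.out = n)
  rr <- start_point[1] + tt * (end_point[1] - start_point[1])
  cc <- start_point[2] + tt * (end_point[2] - start_point[2])
  out <- data.frame(distance_um = tt * len * field$pixel_size_um)
  for (ch in channels)
    out[[ch]] <- bilinear_sample(field$channels[[ch]], rr, cc)
  out
}

bilinear_sample <- function(m, rr, cc) {
  r0 <- pmin(pmax(floor(rr), 1L), nrow(m) - 1L)
  c0 <- pmin(pmax(floor(cc), 1L), ncol(m) - 1L)
  fr <- rr - r0
  fc <- cc - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}
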