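#' Marker positivity thresholds
#'
#' Per-marker intensity cutoffs in 8-bit a.u.; a nucleus is positive when
#' its mean intensity is strictly greater than the threshold. Defaults are
#' 10 a.u. for HU, green and far-red and 30 a.u. for red.
#'
#' @param ... Named thresholds, e.g. `green = 10, red = 30`; if empty the
#'   defaults above are used.
#' @return Named numeric vector of class `marker_thresholds`.
#' @export
marker_thresholds <- function(...) {
  th <- c(...)
  if (length(th) == 0)
    th <- c(HU = 10, green = 10, red = 30, "far-red" = 10)
  if (is.null(names(th)) || any(names(th) == ""))
    stop("marker_thresholds: all thresholds must be named")
  if (any(th < 0 | th > 255))
    stop("marker_thresholds: thresholds must lie in [0, 255]")
  structure(th, class = "marker_thresholds")
}

#' Mean intensity of a channel over a nucleus mask
#'
#' @param nucleus A nucleus `region_of_interest`.
#' @param channel A [channel_image] (expected background-subtracted, 8-bit).
#' @return Arithmetic mean intensity, a.u.
#' @export
measure_nucleus_intensity <- function(nucleus, channel) {
  stopifnot(inherits(channel, "channel_image"))
  shape <- dim(channel$pixels)
  b <- nucleus$bbox
  if (b[1L] < 0L || b[2L] < 0L || b[3L] > shape[1L] || b[4L] > shape[2L])
    stop("validation error: nucleus mask outside channel shape")
  sub <- channel$pixels[(b[1L] + 1L):b[3L], (b[2L] + 1L):b[4L], drop = FALSE]
  vals <- sub[nucleus$mask]
  if (length(vals) == 0) stop("validation error: empty nucleus mask")
  mean(vals)
}

#' Classify marker positivity of nucleus records
#'
#' Sets `pos_<marker> = mean_<marker> > threshold` (strict inequality, the
#' "cells with >10 a.u. ... counted as Hu+" rule) for every marker in
#' `thresholds`; all other fields are unchanged.
#'
#' @param records Nucleus-record data.frame with `mean_<marker>` columns.
#' @param thresholds A [marker_thresholds].
#' @return The records with `pos_<marker>` logical columns set.
#' @export
classify_positivity <- function(records, thresholds) {
  for (m in names(thresholds)) {
    col <- paste0("mean_", m)
    if (!col %in% names(records))
      stop(sprintf("configuration error: no measured intensity for marker '%s'", m))
    records[[paste0("pos_", m)]] <- records[[col]] > unname(thresholds[m])
  }
  records
}

#' Measure and classify every nucleus of a stack
#'
#' For each marker channel named in `thresholds` and present in the stack:
#' converts to 8-bit, subtracts the rolling-ball background (unless
#' `subtract_marker_background = FALSE`), measures the mean intensity over
#' each nucleus mask, and classifies positivity by strict threshold. Each
#' nucleus is assigned to the ROI containing its centroid (NA if none).
#'
#' @param stack An [image_stack].
#' @param rois List of neurosphere `region_of_interest`.
#' @param nuclei List of nucleus `region_of_interest`.
#' @param thresholds A [marker_thresholds]; every named marker must exist as
#'   a channel label in `stack`.
#' @param params A [preprocess_params] (only `rolling_radius` is used here).
#' @param subtract_marker_background Subtract background before measuring?
#'   Default `TRUE` for uniform intensity semantics across designs.
#' @return Data.frame with one row per nucleus: `nucleus_id`, `roi_id`,
#'   `area`, `centroid_row`, `centroid_col`, `mean_<marker>` and
#'   `pos_<marker>` columns.
#' @export
classify_stack <- function(stack, rois, nuclei, thresholds = marker_thresholds(),
                           params = preprocess_params(),
                           subtract_marker_background = TRUE) {
  markers <- names(thresholds)
  missing <- setdiff(markers, names(stack$channels))
  if (length(missing) > 0)
    stop(sprintf("configuration error: threshold(s) on absent channel(s): %s",
                 paste(missing, collapse = ", ")))
  prepped <- lapply(markers, function(m) {
    ch <- to_8bit(get_channel(stack, m))
    if (subtract_marker_background)
      ch <- subtract_background_rolling(ch, params$rolling_radius)
    ch
  })
  names(prepped) <- markers
  n <- length(nuclei)
  rec <- data.frame(
    nucleus_id = if (n > 0) seq_len(n) else integer(0),
    roi_id = rep(NA_integer_, n),
    area = if (n > 0) vapply(nuclei, `[[`, 0, "area") else numeric(0),
    centroid_row = if (n > 0) vapply(nuclei, function(x) x$centroid[1L], 0) else numeric(0),
    centroid_col = if (n > 0) vapply(nuclei, function(x) x$centroid[2L], 0) else numeric(0))
  for (i in seq_len(n)) {
    for (roi in rois) {
      if (roi_contains(roi, nuclei[[i]]$centroid)) {
        rec$roi_id[i] <- roi$roi_id
        break
      }
    }
  }
  for (m in markers) {
    rec[[paste0("mean_", m)]] <-
      if (n > 0) vapply(nuclei, measure_nucleus_intensity, 0, channel = prepped[[m]])
      else numeric(0)
  }
  classify_positivity(rec, thresholds)
}
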