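#' Particle gate on area and circularity
#'
#' Both intervals are inclusive at both ends, matching the closed printed
#' ranges (e.g. 1,000-50,000 px^2, circularity 0.5-1.0 for neurospheres and
#' 10-1,000 px^2, 0.3-1.0 for nuclei).
#'
#' @param area_min,area_max Area interval, px^2.
#' @param circ_min,circ_max Circularity interval in `[0, 1]`.
#' @return An object of class `particle_gate`.
#' @export
particle_gate <- function(area_min, area_max, circ_min = 0, circ_max = 1) {
  if (area_min < 0 || area_min > area_max)
    stop("particle_gate: need 0 <= area_min <= area_max")
  if (circ_min < 0 || circ_min > circ_max || circ_max > 1)
    stop("particle_gate: need 0 <= circ_min <= circ_max <= 1")
  structure(list(area_min = area_min, area_max = area_max,
                 circ_min = circ_min, circ_max = circ_max),
            class = "particle_gate")
}

# Contour perimeter, Vossepoel-Smeulders corrected chain length:
# 0.980 * (axis-parallel steps) + 1.406 * (diagonal steps) - 0.091 * (corners).
# Raw (1, sqrt(2)) chain lengths overestimate digital-disk perimeters by ~5%,
# which would push disks to circularity ~0.91; the corrected estimator is
# accurate to ~1% so disks sit at 1.0 after capping.
contour_perimeter <- function(contour) {
  n <- nrow(contour)
  if (n < 2L) return(0)
  p <- rbind(contour, contour[1L, , drop = FALSE])
  dx <- diff(p[, 1L]); dy <- diff(p[, 2L])
  step <- abs(dx) + abs(dy)
  ne <- sum(step == 1L); no <- sum(step == 2L)
  dirs <- atan2(dy, dx)
  ncorner <- sum(abs(diff(c(dirs, dirs[1L]))) > 1e-9)
  max(0.980 * ne + 1.406 * no - 0.091 * ncorner, 0)
}

# internal: build one region_of_interest from the pixels of a single label
roi_from_label <- function(lab, value, roi_id, source = "auto") {
  idx <- which(lab == value, arr.ind = TRUE)
  area <- nrow(idx)
  r0 <- min(idx[, 1L]); r1 <- max(idx[, 1L])
  c0 <- min(idx[, 2L]); c1 <- max(idx[, 2L])
  sub <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
  sub[cbind(idx[, 1L] - r0 + 1L, idx[, 2L] - c0 + 1L)] <- TRUE
  perim <- if (area == 1L) 0 else {
    oc <- EBImage::ocontour(sub * 1L)[[1L]]
    contour_perimeter(oc)
  }
  circ <- if (perim <= 0) 1 else min(1, 4 * pi * area / perim^2)
  structure(list(
    roi_id = as.integer(roi_id),
    mask = sub,
    # half-open 0-based bbox (row0, col0, row1, col1)
    bbox = c(r0 - 1L, c0 - 1L, r1, c1),
    area = area,
    perimeter = perim,
    circularity = circ,
    centroid = c(mean(idx[, 1L]) - 1, mean(idx[, 2L]) - 1),
    source = source), class = "region_of_interest")
}

#' Construct a region of interest from a full-size mask
#'
#' @param mask Logical matrix over the whole image.
#' @param roi_id Integer id (>= 1).
#' @param source `"auto"` or `"manual"`.
#' @return A `region_of_interest`.
#' @export
roi_from_mask <- function(mask, roi_id = 1L, source = "manual") {
  mask <- as.matrix(mask) > 0
  if (!any(mask)) stop("roi_from_mask: mask is empty")
  roi_from_label(ifelse(mask, 1L, 0L), 1L, roi_id, source)
}

#' Expand a region of interest to a full-image logical mask
#'
#' @param roi A `region_of_interest`.
#' @param shape `c(rows, cols)` of the target image.
#' @return Logical matrix.
#' @export
roi_full_mask <- function(roi, shape) {
  b <- roi$bbox
  if (b[3L] > shape[1L] || b[4L] > shape[2L] || b[1L] < 0L || b[2L] < 0L)
    stop("roi_full_mask: ROI bbox outside image shape")
  m <- matrix(FALSE, shape[1L], shape[2L])
  m[(b[1L] + 1L):b[3L], (b[2L] + 1L):b[4L]] <- roi$mask
  m
}

# internal: is a 0-based (row, col) point inside the ROI mask?
roi_contains <- function(roi, point) {
  r <- floor(point[1L] + 0.5) + 1L - roi$bbox[1L]
  c <- floor(point[2L] + 0.5) + 1L - roi$bbox[2L]
  r >= 1L && c >= 1L && r <= nrow(roi$mask) && c <= ncol(roi$mask) &&
    roi$mask[r, c]
}

#' @export
print.region_of_interest <- function(x, ...) {
  cat(sprintf("<ROI %d (%s): area=%d px^2, circ=%.3f, centroid=(%.1f, %.1f)>\n",
              x$roi_id, x$source, x$area, x$circularity,
              x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Gate labeled particles by area and circularity
#'
#' Measures each label of a label image (area, contour perimeter,
#' circularity `min(1, 4*pi*A/P^2)`, centroid, bbox) and retains those whose
#' area and circularity both fall inside the gate's closed intervals.
#'
#' @param labels Integer label matrix (0 = background).
#' @param gate A [particle_gate].
#' @param source Source tag for the resulting ROIs.
#' @return List of `region_of_interest`, ordered by label; `roi_id` keeps the
#'   original label, so gaps after gating are expected.
#' @export
find_particles <- function(labels, gate, source = "auto") {
  labels <- as.matrix(labels)
  vals <- sort(unique(labels[labels > 0]))
  out <- list()
  for (v in vals) {
    roi <- roi_from_label(labels, v, v, source)
    if (roi$area >= gate$area_min && roi$area <= gate$area_max &&
        roi$circularity >= gate$circ_min && roi$circularity <= gate$circ_max)
      out[[length(out) + 1L]] <- roi
  }
  out
}

#' Segment neurospheres on the pan-neuronal marker channel
#'
#' The neurosphere stage: 8-bit conversion, inversion, inclusive threshold
#' window, morphological clean (closing-then-opening), distance-transform
#' watershed, then particle gating. With the default gate
#' (1,000-50,000 px^2, circularity 0.5-1.0) this reproduces the automatic
#' neurosphere detection; the interactive manual review is replaced by ROI
#' include/exclude files (see [manual_rois_from_file]).
#'
#' @param hu Single [channel_image] (the HU channel).
#' @param params A [preprocess_params]; `invert`, `threshold_lo/hi`,
#'   `morph_radius` and `watershed_min_distance` are used.
#' @param gate A [particle_gate] (default the neurosphere gate).
#' @return List of `region_of_interest` with `source = "auto"`.
#' @export
segment_neurospheres <- function(hu, params = preprocess_params(threshold_hi = 100,
                                                                watershed_min_distance = 25),
                                 gate = particle_gate(1000, 50000, 0.5, 1.0)) {
  stopifnot(inherits(hu, "channel_image"))
  img <- to_8bit(hu)
  if (params$invert) img <- invert_image(img)
  mask <- threshold_window(img, params$threshold_lo, params$threshold_hi)
  mask <- morphological_clean(mask, params$morph_radius)
  lab <- watershed_split(mask, params$watershed_min_distance)
  find_particles(lab, gate, source = "auto")
}

#' Segment nuclei on the DAPI channel within one region of interest
#'
#' The nucleus stage: 8-bit conversion, rolling-ball background subtraction,
#' optional inversion, inclusive threshold window, disk median filter,
#' distance-transform watershed, particle gating (default 10-1,000 px^2,
#' circularity 0.3-1.0). A nucleus belongs to the ROI iff its centroid lies
#' inside the ROI mask; returned coordinates are in full-image frame.
#'
#' @param dapi [channel_image] (DAPI channel).
#' @param roi Parent `region_of_interest`.
#' @param params A [preprocess_params].
#' @param gate A [particle_gate].
#' @return List of nucleus `region_of_interest`s whose centroids fall inside
#'   `roi`.
#' @export
segment_nuclei_in_roi <- function(dapi, roi,
                                  params = preprocess_params(),
                                  gate = particle_gate(10, 1000, 0.3, 1.0)) {
  stopifnot(inherits(dapi, "channel_image"))
  shape <- dim(dapi$pixels)
  b <- roi$bbox
  if (b[1L] < 0L || b[2L] < 0L || b[3L] > shape[1L] || b[4L] > shape[2L])
    stop("segment_nuclei_in_roi: ROI lies outside the DAPI image")
  # crop to the ROI bbox padded by the rolling radius so the background
  # estimate at the ROI edge has full context
  pad <- ceiling(params$rolling_radius)
  r0 <- max(b[1L] + 1L - pad, 1L); r1 <- min(b[3L] + pad, shape[1L])
  c0 <- max(b[2L] + 1L - pad, 1L); c1 <- min(b[4L] + pad, shape[2L])
  crop <- channel_image(dapi$pixels[r0:r1, c0:c1, drop = FALSE],
                        dtype_max = dapi$dtype_max,
                        channel_label = dapi$channel_label)
  img <- to_8bit(crop)
  img <- subtract_background_rolling(img, params$rolling_radius)
  if (params$invert) img <- invert_image(img)
  mask <- threshold_window(img, params$threshold_lo, params$threshold_hi)
  # restrict to the ROI before splitting so neighbouring spheres don't leak in
  roi_crop <- roi_full_mask(roi, shape)[r0:r1, c0:c1, drop = FALSE]
  mask <- mask & roi_crop
  mask <- px(median_filter(mask * 1, params$median_radius)) > 0.5
  lab <- watershed_split(mask, params$watershed_min_distance)
  nuclei <- find_particles(lab, gate, source = "auto")
  # shift to full-image coordinates, keep centroid-inside nuclei
  out <- list()
  for (nuc in nuclei) {
    nuc$bbox <- nuc$bbox + c(r0 - 1L, c0 - 1L, r0 - 1L, c0 - 1L)
    nuc$centroid <- nuc$centroid + c(r0 - 1L, c0 - 1L)
    if (roi_contains(roi, nuc$centroid)) out[[length(out) + 1L]] <- nuc
  }
  for (i in seq_along(out)) {
    out[[i]]$roi_id <- i
    out[[i]]$parent_roi_id <- roi$roi_id
  }
  out
}

#' Manual regions of interest from a polygon file
#'
#' Reads a polygon ROI file (see [read_roi_file]) and rasterizes the
#' included entries; manual ROIs are trusted, so no particle gate applies.
#'
#' @param path Polygon ROI file path.
#' @param shape `c(rows, cols)` of the target image.
#' @return List of `region_of_interest` with `source = "manual"`.
#' @export
manual_rois_from_file <- function(path, shape) {
  read_roi_file(path, shape)
}
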