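#' Preprocessing parameters for one segmentation stage
#'
#' Bundles the image-conditioning knobs one stage composes: optional
#' inversion, rolling-ball background subtraction, median filtering, an
#' inclusive intensity threshold window, morphological cleaning, and the
#' watershed seed spacing. Units are px (radii) and 8-bit a.u. (thresholds).
#'
#' @param invert Apply 8-bit inversion before thresholding? The intensity
#'   windows of the source macros (e.g. 0-13 a.u. for DAPI) select the
#'   bright signal on the inverted image.
#' @param rolling_radius Rolling-ball background radius, px (default 30).
#' @param median_radius Median filter disk radius, px (default 1).
#' @param threshold_lo,threshold_hi Inclusive intensity window, a.u. in
#'   `[0, 255]`.
#' @param morph_radius Disk radius of the morphological clean
#'   (closing-then-opening), px; default 25, the midpoint of the 20-30 px
#'   range used for neurosphere consolidation.
#' @param watershed_min_distance Minimum separation of watershed seed maxima,
#'   px (default 5, so nuclei of radius >= 4 px separate).
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(invert = TRUE, rolling_radius = 30,
                              median_radius = 1, threshold_lo = 0,
                              threshold_hi = 13, morph_radius = 25,
                              watershed_min_distance = 5) {
  if (threshold_lo < 0 || threshold_hi > 255 || threshold_lo > threshold_hi)
    stop("preprocess_params: need 0 <= threshold_lo <= threshold_hi <= 255")
  if (rolling_radius < 1 || median_radius < 1 || morph_radius < 1 ||
      watershed_min_distance < 1)
    stop("preprocess_params: all radii must be >= 1 px")
  structure(list(invert = isTRUE(invert), rolling_radius = rolling_radius,
                 median_radius = median_radius, threshold_lo = threshold_lo,
                 threshold_hi = threshold_hi, morph_radius = morph_radius,
                 watershed_min_distance = watershed_min_distance),
            class = "preprocess_params")
}

#' Convert an image to 8-bit
#'
#' Linear map of `[0, dtype_max]` onto `[0, 255]` with round-half-up;
#' 8-bit input is returned unchanged (idempotent).
#'
#' @param img A [channel_image].
#' @return A [channel_image] with `dtype_max = 255`.
#' @export
to_8bit <- function(img) {
  stopifnot(inherits(img, "channel_image"))
  if (img$dtype_max == 255) return(img)
  p <- floor(img$pixels / img$dtype_max * 255 + 0.5)
  rewrap(img, p, dtype_max = 255)
}

#' Invert an 8-bit image
#'
#' Each pixel `p` becomes `255 - p`; an involution.
#'
#' @param img An 8-bit [channel_image].
#' @return The inverted [channel_image].
#' @export
invert_image <- function(img) {
  stopifnot(inherits(img, "channel_image"))
  if (img$dtype_max != 255)
    stop("invert_image: input must be 8-bit (dtype_max = 255)")
  rewrap(img, 255 - img$pixels)
}

# internal: disk structuring element of Euclidean radius r (odd-sized brush)
disk_brush <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")

# internal: replicate-pad a matrix by r on every side (edge handling for
# morphology, which would otherwise see zeros beyond the border)
pad_replicate <- function(m, r) {
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci, drop = FALSE]
}

crop_pad <- function(m, r, nr, nc) {
  m[(r + 1L):(r + nr), (r + 1L):(r + nc), drop = FALSE]
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background as the grayscale morphological opening of
#' the image with a disk structuring element of the given radius, and
#' subtracts it (clipped to `[0, 255]`). Objects smaller than the element
#' do not enter the background estimate, so they survive subtraction
#' unchanged; the result never exceeds the input at any pixel
#' (anti-extensive).
#'
#' @param img An 8-bit [channel_image].
#' @param radius Structuring-element radius, px (>= 1).
#' @return Background-subtracted [channel_image].
#' @export
subtract_background_rolling <- function(img, radius = 30) {
  stopifnot(inherits(img, "channel_image"))
  if (radius < 1) stop("subtract_background_rolling: radius must be >= 1 px")
  p <- img$pixels
  r <- as.integer(radius)
  # EBImage grayscale morphology operates on [0, 1] intensities
  bg <- crop_pad(as.matrix(EBImage::opening(pad_replicate(p / 255, r),
                                            disk_brush(r))),
                 r, nrow(p), ncol(p)) * 255
  out <- pmin(pmax(p - bg, 0), 255)
  rewrap(img, out)
}

# internal: disk-neighborhood offsets (dr, dc) with dr^2 + dc^2 <= r^2
disk_offsets <- function(r) {
  s <- seq.int(-floor(r), floor(r))
  g <- expand.grid(dr = s, dc = s)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

#' Median filter with a disk neighborhood
#'
#' Replaces each pixel by the median over the Euclidean disk of the given
#' radius; borders are handled by edge replication. Radius 1 gives the
#' 5-pixel cross neighborhood.
#'
#' @param img A [channel_image] or bare numeric matrix.
#' @param radius Neighborhood radius, px (>= 1).
#' @return Filtered image of the same type as the input.
#' @export
median_filter <- function(img, radius = 1) {
  if (radius < 1) stop("median_filter: radius must be >= 1 px")
  p <- px(img)
  nr <- nrow(p); nc <- ncol(p)
  off <- disk_offsets(radius)
  vals <- matrix(0, nrow = nr * nc, ncol = nrow(off))
  for (k in seq_len(nrow(off))) {
    ri <- pmin(pmax(seq_len(nr) + off$dr[k], 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + off$dc[k], 1L), nc)
    vals[, k] <- p[ri, ci]
  }
  # row-wise median via sorted order statistics (odd and even neighborhood sizes)
  m <- ncol(vals)
  srt <- matrix(vals[order(row(vals), vals)], nrow = nr * nc, byrow = TRUE)
  med <- if (m %% 2L == 1L) srt[, (m + 1L) %/% 2L]
         else (srt[, m %/% 2L] + srt[, m %/% 2L + 1L]) / 2
  rewrap(img, matrix(med, nr, nc))
}

#' Inclusive intensity threshold window
#'
#' The mask is true exactly where `lo <= pixel <= hi` (both bounds
#' inclusive), matching the closed windows printed by common threshold
#' dialogs.
#'
#' @param img An 8-bit [channel_image] or matrix.
#' @param lo,hi Window bounds, a.u. in `[0, 255]`, `lo <= hi`.
#' @return Logical matrix (`binary_mask`).
#' @export
threshold_window <- function(img, lo, hi) {
  if (lo > hi) stop("threshold_window: lo must not exceed hi")
  if (lo < 0 || hi > 255) stop("threshold_window: window must lie in [0, 255]")
  p <- px(img)
  p >= lo & p <= hi
}

#' Morphological clean of a binary mask
#'
#' Binary closing followed by opening, both with a disk of the given radius:
#' closing fills holes and gaps smaller than the element (consolidating a
#' speckled stain into one blob), opening then removes protrusions and
#' specks smaller than the element.
#'
#' @param mask Logical matrix.
#' @param radius Disk radius, px (>= 1).
#' @return Cleaned logical matrix.
#' @export
morphological_clean <- function(mask, radius = 25) {
  if (radius < 1) stop("morphological_clean: radius must be >= 1 px")
  b <- disk_brush(radius)
  r <- as.integer(radius)
  m <- pad_replicate(mask * 1, r)
  m <- EBImage::closing(m, b)
  m <- EBImage::opening(m, b)
  crop_pad(as.matrix(m), r, nrow(mask), ncol(mask)) > 0.5
}

#' Label connected components of a binary mask
#'
#' 4-connected component labeling; background is 0, components are labeled
#' `1..K` in scan order.
#'
#' @param mask Logical matrix.
#' @return Integer label matrix.
#' @export
label_components <- function(mask) {
  lab <- as.matrix(EBImage::bwlabel(mask * 1))
  storage.mode(lab) <- "integer"
  lab
}

#' Split touching particles by distance-transform watershed
#'
#' Connected foreground is partitioned by watershed on the Euclidean
#' distance transform: seeds are the distance-transform local maxima, with
#' maxima closer than `min_distance` merged into one seed, and every
#' foreground pixel is assigned to exactly one seed by deterministic region
#' growing (label 0 = background). A component containing a single seed is
#' returned whole, so without touching objects the result equals connected
#' component labeling.
#'
#' @param mask Logical matrix.
#' @param min_distance Minimum seed separation, px.
#' @return Integer label matrix, labels `1..K` in scan order.
#' @export
watershed_split <- function(mask, min_distance = 5) {
  mask <- as.matrix(mask) > 0
  if (!any(mask)) {
    lab <- matrix(0L, nrow(mask), ncol(mask))
    return(lab)
  }
  dm <- as.matrix(EBImage::distmap(mask * 1))
  # local maxima of the distance transform, plateau-tolerant
  mx <- dm >= as.matrix(EBImage::dilate(dm, disk_brush(min_distance))) & mask
  # merge maxima closer than min_distance into single seeds (each maximum
  # grown by half the spacing; grown regions touch iff maxima are nearer
  # than min_distance)
  seed_lab <- label_components(
    as.matrix(EBImage::dilate(mx * 1, disk_brush(max(1, floor(min_distance / 2))))) > 0.5)
  seed_lab[!mx] <- 0L
  lab <- as.matrix(EBImage::propagate(dm, EBImage::Image(seed_lab), mask = mask))
  storage.mode(lab) <- "integer"
  relabel_sequential(lab)
}

# internal: renumber labels to 1..K in column-major scan order
relabel_sequential <- function(lab) {
  u <- unique(lab[lab > 0L])
  if (length(u) == 0L) return(lab)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  out <- lab
  out[lab > 0L] <- map[lab[lab > 0L]]
  out
}
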