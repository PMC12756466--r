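# parse a marker-combination string like "SOX10+PHOX2B+HU-" into
# (marker, sign) pairs; markers are matched longest-first against the known
# marker set so hyphenated names ("far-red+") parse unambiguously
parse_combination <- function(combo, markers) {
  markers <- markers[order(-nchar(markers))]
  pos <- 1L
  out_m <- character(0); out_s <- logical(0)
  while (pos <= nchar(combo)) {
    rest <- substring(combo, pos)
    hit <- markers[startsWith(rest, markers)][1L]
    if (is.na(hit))
      stop(sprintf("cannot parse marker combination '%s' at '%s' (known markers: %s)",
                   combo, rest, paste(markers, collapse = ", ")))
    sign_ch <- substring(rest, nchar(hit) + 1L, nchar(hit) + 1L)
    if (!sign_ch %in% c("+", "-"))
      stop(sprintf("marker '%s' in combination '%s' must be followed by + or -",
                   hit, combo))
    out_m <- c(out_m, hit); out_s <- c(out_s, sign_ch == "+")
    pos <- pos + nchar(hit) + 1L
  }
  data.frame(marker = out_m, positive = out_s, stringsAsFactors = FALSE)
}

#' Integrate nucleus records into one per-neurosphere summary
#'
#' For each requested marker combination (conjunctions such as
#' `"SOX10+PHOX2B+"`, negations allowed, e.g. `"SOX10+PHOX2B+HU-"`), counts
#' the nuclei matching every term and reports the proportion of `n_nuclei`.
#' With zero nuclei the proportions are undefined and flagged (`NA` with
#' `proportions_defined = FALSE`).
#'
#' @param records Nucleus-record data.frame (see [classify_stack]).
#' @param roi_id Neurosphere id the records belong to.
#' @param combinations Character vector of combinations.
#' @param image_id Image identifier carried into the summary.
#' @return An object of class `neurosphere_summary`.
#' @export
summarize_roi <- function(records, roi_id, combinations, image_id = "") {
  records <- records[!is.na(records$roi_id) & records$roi_id == roi_id, , drop = FALSE]
  n <- nrow(records)
  known <- sub("^pos_", "", grep("^pos_", names(records), value = TRUE))
  counts <- integer(length(combinations))
  names(counts) <- combinations
  for (combo in combinations) {
    terms <- parse_combination(combo, known)
    keep <- rep(TRUE, n)
    for (k in seq_len(nrow(terms)))
      keep <- keep & (records[[paste0("pos_", terms$marker[k])]] == terms$positive[k])
    counts[combo] <- sum(keep)
  }
  props <- if (n > 0) counts / n else setNames(rep(NA_real_, length(counts)), names(counts))
  structure(list(image_id = image_id, roi_id = as.integer(roi_id),
                 n_nuclei = n, n_positive = as.list(counts),
                 proportion = as.list(props),
                 proportions_defined = n > 0),
            class = "neurosphere_summary")
}

#' @export
print.neurosphere_summary <- function(x, ...) {
  cat(sprintf("<neurosphere_summary ROI %d: %d nuclei; %s>\n", x$roi_id,
              x$n_nuclei,
              paste(sprintf("%s=%d", names(x$n_positive),
                            unlist(x$n_positive)), collapse = ", ")))
  invisible(x)
}

#' Distances from points to a spheroid border
#'
#' For each point, the distance is the minimum Euclidean distance to any
#' boundary pixel of the spheroid mask; the five largest distances are
#' returned sorted descending (the "five data points recorded from the
#' border of each spheroid", taking the longest projections / most distant
#' cells). Distances are in pixel units.
#'
#' @param spheroid A `region_of_interest`.
#' @param points n x 2 matrix of 0-based `(row, col)` points.
#' @param shape `c(rows, cols)` of the image the points live in.
#' @param metric_label `"cell_distance"` or `"neurite_length"`.
#' @param spheroid_id Id carried into the measurement.
#' @return An object of class `migration_measurement` with fields
#'   `spheroid_id`, `distances` (length 5, descending) and `metric_label`.
#' @export
measure_border_distances <- function(spheroid, points, shape = NULL,
                                     metric_label = c("cell_distance", "neurite_length"),
                                     spheroid_id = spheroid$roi_id) {
  metric_label <- match.arg(metric_label)
  points <- matrix(as.numeric(points), ncol = 2L)
  if (is.null(shape)) shape <- c(spheroid$bbox[3L], spheroid$bbox[4L])
  shape <- pmax(shape, c(spheroid$bbox[3L], spheroid$bbox[4L]))
  fm <- roi_full_mask(spheroid, shape)
  bnd_mask <- mask_boundary(fm)
  # a point on the border itself measures 0; only strictly interior points
  # are invalid
  interior <- fm & !bnd_mask
  outside <- !apply(points, 1L, function(p) {
    r <- floor(p[1L] + 0.5) + 1L; c <- floor(p[2L] + 0.5) + 1L
    r >= 1L && c >= 1L && r <= nrow(interior) && c <= ncol(interior) &&
      interior[r, c]
  })
  if (sum(outside) < 5L)
    stop(sprintf("validation error: need >= 5 points outside the spheroid, got %d",
                 sum(outside)))
  bnd <- which(bnd_mask, arr.ind = TRUE) - 1  # 0-based
  d <- apply(points[outside, , drop = FALSE], 1L, function(p)
    sqrt(min((bnd[, 1L] - p[1L])^2 + (bnd[, 2L] - p[2L])^2)))
  structure(list(spheroid_id = as.integer(spheroid_id),
                 distances = sort(d, decreasing = TRUE)[1:5],
                 metric_label = metric_label),
            class = "migration_measurement")
}

#' Detect emigrated cells / neurite tips outside a spheroid
#'
#' Segments marker-positive particles with the nucleus-stage preprocessing
#' primitives, discards particles lying entirely inside the spheroid mask,
#' and returns for each remaining particle the pixel of its mask farthest
#' from the spheroid border (so neurite tips, not centroids, set the
#' measured length).
#'
#' @param marker A [channel_image] (e.g. TUJ1 or HNK1).
#' @param spheroid A `region_of_interest` covering the spheroid.
#' @param params A [preprocess_params].
#' @param gate A [particle_gate] (default the permissive multichannel gate
#'   0.001-1,000 px^2, circularity 0.1-1.0).
#' @return n x 2 matrix of 0-based `(row, col)` points, one per particle.
#' @export
detect_emigrated_points <- function(marker, spheroid,
                                    params = preprocess_params(),
                                    gate = particle_gate(0.001, 1000, 0.1, 1.0)) {
  stopifnot(inherits(marker, "channel_image"))
  shape <- dim(marker$pixels)
  img <- to_8bit(marker)
  img <- subtract_background_rolling(img, params$rolling_radius)
  if (params$invert) img <- invert_image(img)
  mask <- threshold_window(img, params$threshold_lo, params$threshold_hi)
  mask <- px(median_filter(mask * 1, params$median_radius)) > 0.5
  sph <- roi_full_mask(spheroid, shape)
  mask <- mask & !sph  # only signal outside the spheroid
  lab <- watershed_split(mask, params$watershed_min_distance)
  particles <- find_particles(lab, gate, source = "auto")
  if (length(particles) == 0) return(matrix(numeric(0), ncol = 2L))
  # distance of every outside pixel to the spheroid (border)
  dist_out <- as.matrix(EBImage::distmap((!sph) * 1))
  pts <- t(vapply(particles, function(p) {
    b <- p$bbox
    idx <- which(p$mask, arr.ind = TRUE)
    full <- cbind(idx[, 1L] + b[1L], idx[, 2L] + b[2L])  # 1-based full coords
    dd <- dist_out[full]
    best <- which.max(dd)
    c(full[best, 1L] - 1, full[best, 2L] - 1)
  }, numeric(2L)))
  pts
}
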