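#' Read a multi-plane TIFF as an image stack
#'
#' Planes are returned in file order with the supplied labels attached;
#' channel identity is by the label list, never by TIFF metadata. The source
#' bit depth is preserved in `dtype_max` (255 for 8-bit, 65535 for 16-bit).
#'
#' @param path TIFF file with >= 1 grayscale plane.
#' @param channel_labels One label per plane, e.g.
#'   `c("DAPI", "green", "red", "far-red")`.
#' @return An [image_stack].
#' @export
read_stack <- function(path, channel_labels) {
  if (!file.exists(path)) stop(sprintf("input error: no such file '%s'", path))
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (length(planes) != length(channel_labels))
    stop(sprintf(
      "configuration error: %d plane(s) in '%s' but %d channel label(s)",
      length(planes), path, length(channel_labels)))
  chans <- lapply(seq_along(planes), function(i) {
    p <- planes[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # tolerate gray-as-RGB planes
    bits <- attr(planes[[i]], "bits.per.sample")
    if (is.null(bits)) bits <- if (max(p) > 255) 16L else 8L
    channel_image(matrix(as.numeric(p), nrow(p), ncol(p)),
                  dtype_max = if (bits > 8) 65535 else 255,
                  channel_label = channel_labels[i])
  })
  image_stack(chans)
}

#' Write an image stack to a multi-plane TIFF
#'
#' Integer intensities round-trip bit-exactly through [read_stack].
#'
#' @param stack An [image_stack].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  planes <- lapply(stack$channels, function(ch) ch$pixels / ch$dtype_max)
  bits <- if (any(vapply(stack$channels, `[[`, 0, "dtype_max") > 255)) 16L else 8L
  tiff::writeTIFF(planes, path, bits.per.sample = bits)
  invisible(path)
}

# Polygon ROI file dialect: plain CSV with columns
#   roi_id, include, vertex, row, col
# one row per vertex, vertices in order, polygon implicitly closed.
# Coordinates are 0-based pixel centers; a pixel belongs to the polygon if
# its center is inside (even-odd rule, half-open rasterization).

#' Write a polygon ROI file
#' @param entries List with elements `roi_id`, `include` (logical), and
#'   `vertices` (n x 2 matrix of 0-based (row, col)).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_file <- function(entries, path) {
  rows <- do.call(rbind, lapply(entries, function(e) {
    v <- as.matrix(e$vertices)
    data.frame(roi_id = e$roi_id, include = isTRUE(e$include),
               vertex = seq_len(nrow(v)), row = v[, 1L], col = v[, 2L])
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# internal: even-odd point-in-polygon for all pixel centers of a grid
rasterize_polygon <- function(vertices, shape) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  if (n < 3L) stop("parse error: polygon needs at least 3 vertices")
  inside <- matrix(FALSE, shape[1L], shape[2L])
  ys <- seq_len(shape[1L]) - 1  # pixel-center rows, 0-based
  for (r in seq_len(shape[1L])) {
    y <- ys[r]
    xcross <- numeric(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      y1 <- v[i, 1L]; y2 <- v[j, 1L]
      if ((y1 > y) != (y2 > y)) {
        x1 <- v[i, 2L]; x2 <- v[j, 2L]
        xcross <- c(xcross, x1 + (y - y1) / (y2 - y1) * (x2 - x1))
      }
    }
    if (length(xcross) > 0) {
      cols0 <- seq_len(shape[2L]) - 1
      cnt <- colSums(outer(xcross, cols0, ">"))
      inside[r, ] <- cnt %% 2L == 1L
    }
  }
  inside
}

#' Read a polygon ROI file and rasterize to masks
#'
#' Entries flagged `include = FALSE` are dropped (the file-based stand-in
#' for the interactive manual review) with a message.
#'
#' @param path ROI file path (see [write_roi_file] for the dialect).
#' @param shape `c(rows, cols)` of the target image.
#' @return List of `region_of_interest` with `source = "manual"`.
#' @export
read_roi_file <- function(path, shape) {
  if (!file.exists(path)) stop(sprintf("input error: no such file '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "include", "vertex", "row", "col")
  if (!all(need %in% names(df)))
    stop("parse error: ROI file must have columns roi_id, include, vertex, row, col")
  out <- list()
  for (id in unique(df$roi_id)) {
    e <- df[df$roi_id == id, , drop = FALSE]
    e <- e[order(e$vertex), , drop = FALSE]
    if (any(e$row < 0 | e$row > shape[1L] - 1 | e$col < 0 | e$col > shape[2L] - 1))
      stop(sprintf("parse error: ROI '%s' has a vertex outside the image", id))
    if (!isTRUE(as.logical(e$include[1L]))) {
      message(sprintf("read_roi_file: ROI '%s' excluded by review flag", id))
      next
    }
    mask <- rasterize_polygon(cbind(e$row, e$col), shape)
    if (!any(mask))
      stop(sprintf("parse error: ROI '%s' rasterizes to an empty mask", id))
    roi <- roi_from_mask(mask, roi_id = length(out) + 1L, source = "manual")
    out[[length(out) + 1L]] <- roi
  }
  out
}

# stable flattened column order for summary CSVs
summary_to_row <- function(s) {
  base <- data.frame(image_id = s$image_id, roi_id = s$roi_id,
                     n_nuclei = s$n_nuclei, stringsAsFactors = FALSE)
  for (combo in names(s$n_positive)) {
    base[[paste0("count_", combo)]] <- s$n_positive[[combo]]
    base[[paste0("prop_", combo)]] <- s$proportion[[combo]]
  }
  base
}

#' Write per-neurosphere summaries to CSV
#'
#' One data row per summary; the first line is a `#`-prefixed comment
#' documenting the column order. Numeric fields are rendered in plain
#' decimal (no scientific notation) at full double precision.
#'
#' @param rows List of `neurosphere_summary` (may be empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(rows, path) {
  if (length(rows) > 0) {
    df <- do.call(rbind, lapply(rows, summary_to_row))
  } else {
    df <- data.frame(image_id = character(0), roi_id = integer(0),
                     n_nuclei = integer(0))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# columns: ", paste(names(df), collapse = ", ")), con)
  num <- vapply(df, is.numeric, TRUE)
  for (nm in names(df)[num])
    df[[nm]] <- vapply(df[[nm]], function(x)
      if (is.na(x)) "NA" else format(x, scientific = FALSE, digits = 15, trim = TRUE),
      "")
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a summary CSV written by [write_summary_csv]
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_summary_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write per-nucleus records to CSV
#' @param records Nucleus-record data.frame (see [classify_stack]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nucleus_csv <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# columns: ", paste(names(records), collapse = ", ")), con)
  num <- vapply(records, is.numeric, TRUE)
  for (nm in names(records)[num])
    records[[nm]] <- vapply(records[[nm]], function(x)
      if (is.na(x)) "NA" else format(x, scientific = FALSE, digits = 15, trim = TRUE),
      "")
  utils::write.table(records, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# internal: 4-connected boundary pixels of a full-size logical mask
mask_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  interior <- mask & shift(mask, 1L, 0L) & shift(mask, -1L, 0L) &
    shift(mask, 0L, 1L) & shift(mask, 0L, -1L)
  mask & !interior
}

#' Write a quality-control overlay image
#'
#' Renders the base channel in gray with ROI outlines in yellow and nucleus
#' outlines colored by positivity class (a fixed palette keyed by the sorted
#' class name, so output is deterministic for fixed inputs). Input pixels
#' are never modified.
#'
#' @param stack An [image_stack]; the first channel is the base layer.
#' @param rois List of `region_of_interest`.
#' @param nuclei List of nucleus `region_of_interest`.
#' @param path Output PNG path.
#' @param nucleus_class Optional character vector, one class per nucleus
#'   (e.g. `"green+"`); unnamed nuclei render cyan.
#' @return `path`, invisibly.
#' @export
write_qc_overlay <- function(stack, rois, nuclei, path, nucleus_class = NULL) {
  base <- stack$channels[[1L]]
  g <- base$pixels / base$dtype_max
  shape <- dim(g)
  img <- array(rep(g, 3L), dim = c(shape, 3L))
  paint <- function(img, pix, rgb) {
    for (k in 1:3) {
      plane <- img[, , k]
      plane[pix] <- rgb[k]
      img[, , k] <- plane
    }
    img
  }
  for (roi in rois) {
    b <- roi$bbox
    if (b[1L] < 0L || b[2L] < 0L || b[3L] > shape[1L] || b[4L] > shape[2L])
      stop("validation error: ROI geometry outside image bounds")
    fm <- roi_full_mask(roi, shape)
    img <- paint(img, which(mask_boundary(fm)), c(1, 1, 0))
  }
  if (length(nuclei) > 0) {
    classes <- if (is.null(nucleus_class)) rep("", length(nuclei)) else nucleus_class
    pal <- grDevices::rainbow(max(1L, length(unique(classes))), s = 0.9, v = 1)
    key <- sort(unique(classes))
    for (i in seq_along(nuclei)) {
      b <- nuclei[[i]]$bbox
      if (b[1L] < 0L || b[2L] < 0L || b[3L] > shape[1L] || b[4L] > shape[2L])
        stop("validation error: nucleus geometry outside image bounds")
      fm <- roi_full_mask(nuclei[[i]], shape)
      col <- if (classes[i] == "") c(0, 1, 1)
             else grDevices::col2rgb(pal[match(classes[i], key)])[, 1L] / 255
      img <- paint(img, which(mask_boundary(fm)), col)
    }
  }
  png::writePNG(img, path)
  invisible(path)
}
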