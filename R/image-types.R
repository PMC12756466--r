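#' @importFrom stats median rnorm runif setNames aov TukeyHSD kruskal.test
#'   wilcox.test p.adjust pnorm rlnorm
#' @importFrom utils write.table read.csv head
NULL

#' Single-channel image
#'
#' The unit all preprocessing operates on: one 2-D grayscale plane together
#' with its channel label and the maximum representable intensity of the
#' source data (255 for 8-bit, 65535 for 16-bit). Intensities are in
#' arbitrary units ("a.u."); all pixel coordinates in this package are
#' 0-based `(row, col)`.
#'
#' @param pixels Numeric matrix (rows x cols) of intensities in
#'   `[0, dtype_max]`.
#' @param dtype_max Maximum representable source intensity (default 255).
#' @param channel_label Free-text channel name, e.g. `"DAPI"`, `"HU"`,
#'   `"green"`.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, dtype_max = 255, channel_label = "") {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("channel_image: pixels must have at least one row and one column")
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > dtype_max))
    stop("channel_image: intensities must lie in [0, dtype_max]")
  structure(
    list(pixels = pixels, dtype_max = dtype_max,
         channel_label = channel_label, pixel_units = "a.u."),
    class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image '%s' %dx%d, dtype_max=%d, range=[%g, %g] a.u.>\n",
              x$channel_label, nrow(x$pixels), ncol(x$pixels),
              as.integer(x$dtype_max), min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Multichannel image stack
#'
#' An ordered collection of [channel_image] planes sharing one shape, with
#' unique channel labels. Channel identity is carried by the user-supplied
#' labels, never by file metadata.
#'
#' @param channels List of [channel_image] objects.
#' @return An object of class `image_stack` with elements `channels` and
#'   `shape` (`c(rows, cols)`).
#' @export
image_stack <- function(channels) {
  if (length(channels) < 1L) stop("image_stack: need at least one channel")
  shapes <- lapply(channels, function(ch) dim(ch$pixels))
  if (length(unique(vapply(shapes, paste, "", collapse = "x"))) != 1L)
    stop("image_stack: all channels must have identical shape")
  labels <- vapply(channels, `[[`, "", "channel_label")
  if (anyDuplicated(labels))
    stop("image_stack: channel labels must be unique")
  structure(list(channels = setNames(channels, labels), shape = shapes[[1L]]),
            class = "image_stack")
}

#' Extract a channel from a stack by label
#' @param stack An [image_stack].
#' @param label Channel label.
#' @return A [channel_image].
#' @export
get_channel <- function(stack, label) {
  ch <- stack$channels[[label]]
  if (is.null(ch))
    stop(sprintf("channel '%s' not present in stack (have: %s)",
                 label, paste(names(stack$channels), collapse = ", ")))
  ch
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack %dx%d, %d channel(s): %s>\n",
              x$shape[1], x$shape[2], length(x$channels),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# internal: accept either a channel_image or a bare matrix, return the matrix
px <- function(img) {
  if (inherits(img, "channel_image")) img$pixels else as.matrix(img)
}

# internal: rebuild a channel_image around new pixels, keeping metadata
rewrap <- function(img, pixels, dtype_max = NULL) {
  if (inherits(img, "channel_image")) {
    channel_image(pixels,
                  dtype_max = if (is.null(dtype_max)) img$dtype_max else dtype_max,
                  channel_label = img$channel_label)
  } else {
    pixels
  }
}
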