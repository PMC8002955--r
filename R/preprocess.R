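#' Rectangular region of interest
#'
#' Pixel rectangle in image coordinates: `x0, y0` is the top-left pixel
#' (0-based, x = column, y = row), `width`/`height` in pixels.
#'
#' @param x0,y0 top-left pixel (0-based).
#' @param width,height extent in pixels (>= 1).
#' @return A `rect` object (named list).
#' @export
rect <- function(x0, y0, width, height) {
  if (width < 1 || height < 1) stop("rect width and height must be >= 1")
  if (x0 < 0 || y0 < 0) stop("rect origin must be non-negative")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "rect")
}

#' Crop a frame to a rectangle
#'
#' `out[r, c] == frame[rect$y0 + r, rect$x0 + c]` in 0-based coordinates;
#' the rectangle must lie fully inside the frame.
#'
#' @param frame intensity matrix.
#' @param r a [rect].
#' @return the cropped matrix of dimension `height x width`.
#' @export
crop_frame <- function(frame, r) {
  stopifnot(inherits(r, "rect"))
  H <- nrow(frame); W <- ncol(frame)
  if (r$y0 + r$height > H || r$x0 + r$width > W)
    stop("rect extends outside the frame (", H, " x ", W, ")")
  frame[r$y0 + seq_len(r$height), r$x0 + seq_len(r$width), drop = FALSE]
}

#' Crop every frame of a stack
#' @param stack an [image_stack].
#' @param r a [rect].
#' @return a cropped [image_stack].
#' @export
crop_stack <- function(stack, r) {
  image_stack(lapply(stack$frames, crop_frame, r = r),
              bit_depth = stack$bit_depth, pixel_size = stack$pixel_size,
              frame_interval = stack$frame_interval, mode = stack$mode)
}

#' Median filter a frame
#'
#' Square-kernel median denoising, the standard pre-segmentation smoothing
#' step (5x5 for the tracking pipeline, 3x3 for the CFL pipeline). Borders
#' are handled by padding; the default replicates edge pixels, which avoids
#' the artificial darkening that zero padding creates along the borders of
#' fluorescence frames. `pad = "zero"` is available for bit-compatibility
#' with implementations that pad with zeros.
#'
#' @param frame intensity matrix.
#' @param kernel odd integer >= 1, the kernel side length.
#' @param pad `"replicate"` (default) or `"zero"`.
#' @return matrix of the same dimensions.
#' @export
median_filter <- function(frame, kernel = 3L, pad = c("replicate", "zero")) {
  pad <- match.arg(pad)
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L)
    stop("kernel must be an odd integer >= 1")
  if (kernel == 1L) return(frame)
  m <- frame
  storage.mode(m) <- "double"
  median_filter_cpp(m, kernel, if (pad == "zero") 1L else 0L)
}

#' Median filter every frame of a stack
#' @inheritParams median_filter
#' @param stack an [image_stack].
#' @return a filtered [image_stack].
#' @export
median_filter_stack <- function(stack, kernel = 3L,
                                pad = c("replicate", "zero")) {
  pad <- match.arg(pad)
  out <- stack
  out$frames <- lapply(stack$frames, median_filter, kernel = kernel, pad = pad)
  out
}

#' Normalize intensity polarity so cells are bright
#'
#' Downstream segmentation always treats cells as bright objects. In
#' fluorescence mode frames already are cells-bright and pass through
#' unchanged; in brightfield mode (dark cells on a bright background) the
#' frame is inverted: `max_value - pixel`. Inversion is an involution.
#'
#' @param frame intensity matrix.
#' @param mode `"fluorescence"` or `"brightfield"`.
#' @param max_value full-scale intensity (255 for 8-bit, 65535 for 16-bit).
#' @return matrix of the same dimensions.
#' @export
normalize_polarity <- function(frame, mode = c("fluorescence", "brightfield"),
                               max_value = 255) {
  mode <- match.arg(mode)
  if (mode == "fluorescence") frame else max_value - frame
}
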