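#' Image stack container
#'
#' An `image_stack` is an ordered sequence of equally sized grayscale frames
#' together with its spatial and temporal calibration. Frames are numeric
#' matrices (rows = image rows = y, columns = x) holding integer intensities
#' in `[0, 2^bit_depth - 1]`. Pixel coordinates throughout the package are
#' 0-based: `x` is the column index increasing rightward, `y` the row index
#' increasing downward, so the centroid of the single pixel at (row r, col c)
#' is `(x = c, y = r)`. Frame indices are 0-based as well.
#'
#' @param frames list of numeric matrices, all with identical dimensions.
#' @param bit_depth 8 or 16.
#' @param pixel_size physical pixel size, micrometres per pixel (> 0).
#' @param frame_interval seconds between consecutive frames (> 0).
#' @param mode `"fluorescence"` (cells bright on dark background) or
#'   `"brightfield"` (cells dark on bright background).
#'
#' @return An object of class `image_stack`.
#' @examples
#' fr <- lapply(1:3, function(i) matrix(i, 4, 5))
#' s <- image_stack(fr, bit_depth = 8, pixel_size = 0.45,
#'                  frame_interval = 0.01, mode = "fluorescence")
#' n_frames(s)
#' @export
image_stack <- function(frames, bit_depth = 8, pixel_size = 1,
                        frame_interval = 1,
                        mode = c("fluorescence", "brightfield")) {
  mode <- match.arg(mode)
  if (!is.list(frames) || length(frames) < 1L)
    stop("'frames' must be a non-empty list of matrices")
  if (!all(vapply(frames, is.matrix, logical(1))))
    stop("every frame must be a matrix")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must have identical dimensions")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  maxv <- 2^bit_depth - 1
  rng <- range(vapply(frames, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > maxv)
    stop("intensities must lie in [0, ", maxv, "]")
  frames <- lapply(frames, function(f) {
    storage.mode(f) <- "double"
    f
  })
  structure(list(frames = frames, bit_depth = as.integer(bit_depth),
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 mode = mode),
            class = "image_stack")
}

#' @rdname image_stack
#' @param x,object an `image_stack`.
#' @export
n_frames <- function(x) length(x$frames)

#' @rdname image_stack
#' @export
frame_dim <- function(x) dim(x$frames[[1]])

#' Maximum representable intensity of a stack or bit depth
#' @param x an `image_stack` or a bit depth (8 or 16).
#' @return `2^bit_depth - 1`.
#' @export
max_intensity <- function(x) {
  bd <- if (inherits(x, "image_stack")) x$bit_depth else as.integer(x)
  2^bd - 1
}

#' @export
print.image_stack <- function(x, ...) {
  d <- frame_dim(x)
  cat(sprintf(
    "<image_stack> %d frame(s) of %d x %d px, %d-bit, %s\n", n_frames(x),
    d[1], d[2], x$bit_depth, x$mode))
  cat(sprintf("  pixel size %.4g um/px, frame interval %.4g s (%.4g fps)\n",
              x$pixel_size, x$frame_interval, 1 / x$frame_interval))
  invisible(x)
}

#' @export
`[.image_stack` <- function(x, i) {
  image_stack(x$frames[i], bit_depth = x$bit_depth,
              pixel_size = x$pixel_size, frame_interval = x$frame_interval,
              mode = x$mode)
}
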