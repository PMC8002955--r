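#' Temporal Z-projection of an image stack
#'
#' Reduces the stack along the temporal ("z") axis, pixel by pixel, with one
#' of the six classic projection types: `average`, `sum`, `std` (standard
#' deviation), `median`, `min`, `max`. The result is real-valued; no clipping
#' or requantization is applied (use [rescale_to_8bit()] for display).
#' Standard deviation uses the sample (n-1) denominator, matching the ImageJ
#' behavior; set `population = TRUE` for the n denominator.
#'
#' @param stack an [image_stack].
#' @param method one of `"average", "sum", "std", "median", "min", "max"`.
#' @param population use the population (n) variance denominator for `std`.
#' @return a `projection_image`: numeric matrix with attribute `method`.
#' @examples
#' s <- image_stack(list(matrix(0:3, 2), matrix(2:5, 2)))
#' z_project(s, "average")
#' @export
z_project <- function(stack,
                      method = c("average", "sum", "std", "median",
                                 "min", "max"),
                      population = FALSE) {
  method <- match.arg(method)
  fr <- stack$frames
  n <- length(fr)
  out <- switch(
    method,
    sum = Reduce(`+`, fr),
    average = Reduce(`+`, fr) / n,
    min = Reduce(pmin, fr),
    max = Reduce(pmax, fr),
    std = {
      if (n == 1L) {
        matrix(if (population) 0 else NA_real_, nrow(fr[[1]]), ncol(fr[[1]]))
      } else {
        s1 <- Reduce(`+`, fr)
        s2 <- Reduce(`+`, lapply(fr, function(f) f^2))
        ss <- pmax(s2 - s1^2 / n, 0)   # guard tiny negative rounding
        sqrt(ss / (if (population) n else n - 1L))
      }
    },
    median = {
      a <- array(unlist(fr, use.names = FALSE),
                 dim = c(nrow(fr[[1]]), ncol(fr[[1]]), n))
      apply(a, c(1, 2), median)
    })
  structure(out, method = method, class = c("projection_image", "matrix"))
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf("<projection_image> %s projection, %d x %d px, range [%g, %g]\n",
              attr(x, "method"), nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Rescale a real-valued projection to displayable 8-bit
#' @param x numeric matrix.
#' @return integer-valued matrix in `[0, 255]` (linear min-max rescale;
#'   constant input maps to 0).
#' @export
rescale_to_8bit <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(matrix(0, nrow(x), ncol(x)))
  round((x - r[1]) / (r[2] - r[1]) * 255)
}

#' ROI tonality over time (Z-axis profile)
#'
#' For each frame, the arithmetic mean intensity of the pixels inside the
#' rectangular ROI — the classic Plot-Z-axis-profile measurement. The mean
#' tonality serves as a proxy of local hematocrit: high tonality corresponds
#' to low hematocrit, low tonality to high hematocrit (in brightfield, cells
#' darken the ROI).
#'
#' @param stack an [image_stack].
#' @param roi a [rect] inside the frame.
#' @return data frame `frame` (0-based), `mean_intensity`.
#' @export
z_axis_profile <- function(stack, roi) {
  d <- frame_dim(stack)
  if (roi$y0 + roi$height > d[1] || roi$x0 + roi$width > d[2])
    stop("roi extends outside the frame")
  m <- vapply(stack$frames,
              function(f) mean(crop_frame(f, roi)), numeric(1))
  data.frame(frame = seq_along(stack$frames) - 1L, mean_intensity = m)
}
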