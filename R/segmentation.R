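#' Iterative intermeans threshold
#'
#' Computes the automatic global threshold as the fixed point of the
#' intermeans (Ridler-Calvard) iteration: starting from the global mean
#' `t0`, each step splits the pixels at the current level and moves the
#' level to the midpoint of the two class means,
#' `t_{k+1} = (mean(pixels <= t_k) + mean(pixels > t_k)) / 2`
#' (average of background and average of objects, halved), stopping when the
#' level changes by less than `tol` or after `max_iter` steps. Pixels equal
#' to the level count as background, so after polarity normalization the
#' object class is strictly brighter than the level.
#'
#' @param frame intensity matrix with at least two distinct values.
#' @param tol convergence tolerance in intensity units.
#' @param max_iter maximum number of iterations (`max_iter = 1` gives the
#'   single-pass variant).
#' @return list with `level` (the threshold), `iterations`, `converged`.
#' @examples
#' f <- matrix(c(10, 10, 200, 200), 2)
#' iterative_threshold(f)$level  # 105
#' @export
iterative_threshold <- function(frame, tol = 0.5, max_iter = 100L) {
  v <- as.numeric(frame)
  if (length(unique(v)) < 2L)
    stop("constant image: no background/object split exists")
  t_cur <- mean(v)
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    lo <- v[v <= t_cur]
    hi <- v[v > t_cur]
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t_cur) < tol) {
      t_cur <- t_new
      converged <- TRUE
      break
    }
    t_cur <- t_new
  }
  list(level = t_cur, iterations = iterations, converged = converged)
}

#' Binarize a frame at a threshold level
#'
#' Foreground is strictly above the level: `out[r, c] <- frame[r, c] > level`.
#'
#' @param frame intensity matrix.
#' @param level threshold in intensity units.
#' @return logical matrix (TRUE = foreground).
#' @export
binarize <- function(frame, level) {
  frame > level
}

#' Sobel gradient magnitude
#'
#' Approximates the image intensity gradient with the standard 3x3 Sobel
#' kernels and returns the per-pixel magnitude `sqrt(Gx^2 + Gy^2)`. Borders
#' are handled by edge replication. The magnitude map outlines object edges;
#' it is used for edge display/overlays, while object extraction itself works
#' on the binarized image (filled components give better-defined centroids
#' than edge rings).
#'
#' @param frame intensity matrix, at least 3x3.
#' @return numeric matrix of gradient magnitudes, same dimensions.
#' @export
sobel_edges <- function(frame) {
  H <- nrow(frame); W <- ncol(frame)
  if (H < 3L || W < 3L) stop("frame must be at least 3x3")
  p <- frame[c(1, 1:H, H), c(1, 1:W, W)]  # replicate-pad by 1
  s <- function(dr, dc) p[dr + 1:H, dc + 1:W]
  # x gradient: [-1 0 1; -2 0 2; -1 0 1] (columns left -> right)
  gx <- (s(0, 2) + 2 * s(1, 2) + s(2, 2)) - (s(0, 0) + 2 * s(1, 0) + s(2, 0))
  # y gradient: transpose pattern (rows top -> bottom)
  gy <- (s(2, 0) + 2 * s(2, 1) + s(2, 2)) - (s(0, 0) + 2 * s(0, 1) + s(0, 2))
  sqrt(gx^2 + gy^2)
}

#' Wand (tolerance) region selection
#'
#' Reimplements the ImageJ wand tool: starting from a seed pixel, selects the
#' maximal 8-connected region whose pixel values all lie within
#' `value(seed) - tolerance` to `value(seed) + tolerance`.
#'
#' @param frame intensity matrix.
#' @param x,y seed pixel (0-based column / row).
#' @param tolerance non-negative intensity tolerance.
#' @return logical mask of the selected region.
#' @export
wand_select <- function(frame, x, y, tolerance = 0) {
  H <- nrow(frame); W <- ncol(frame)
  if (tolerance < 0) stop("tolerance must be >= 0")
  if (x < 0 || x >= W || y < 0 || y >= H)
    stop("seed point (", x, ", ", y, ") outside the frame")
  m <- frame
  storage.mode(m) <- "double"
  wand_select_cpp(m, as.integer(y), as.integer(x), tolerance)
}
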