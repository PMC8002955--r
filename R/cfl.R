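#' Channel-wall model
#'
#' The wall is supplied by the user as a piecewise-linear polyline of
#' `(x, y)` vertices (0-based pixel coordinates), mirroring the manual step
#' of selecting the channel wall. The polyline is interpolated to one wall
#' row coordinate per integer column over the covered span.
#'
#' @param x,y polyline vertex coordinates (columns / rows, 0-based); `x`
#'   must be non-decreasing with at least one vertex. A single vertex (or
#'   equal `y`) describes a straight horizontal wall.
#' @param side `"upper"` (CFL measured scanning downward, increasing y) or
#'   `"lower"` (scanning upward).
#' @param span optional integer column range `c(first, last)` to cover;
#'   defaults to `range(round(x))`.
#' @return a `wall_model`: list with `side`, `columns`, `wall_y`.
#' @export
wall_model <- function(x, y, side = c("upper", "lower"), span = NULL) {
  side <- match.arg(side)
  if (length(x) != length(y) || length(x) < 1L)
    stop("x and y must have equal positive length")
  if (is.unsorted(x)) stop("polyline x coordinates must be non-decreasing")
  if (is.null(span)) span <- range(round(x))
  columns <- seq(span[1], span[2])
  wall_y <- if (length(x) == 1L) rep(y, length(columns)) else
    approx(x, y, xout = columns, rule = 2)$y
  structure(list(side = side, columns = as.integer(columns), wall_y = wall_y),
            class = "wall_model")
}

#' Temporal extreme-intensity image of a sequence
#'
#' Evaluates the intensity of each pixel across the whole frame sequence and
#' keeps the extreme that corresponds to maximum cell signal: the per-pixel
#' maximum of the polarity-normalized (cells-bright) frames, shown on the
#' stack's native intensity scale. For a fluorescence stack this is the
#' literal pixel-wise maximum; for a brightfield stack it is the pixel-wise
#' minimum of the raw frames (equivalently, the maximum after intensity
#' inversion). In a brightfield sequence the result separates the region
#' cells traverse (dark core: a pixel is dark as soon as a cell ever covered
#' it) from the cell-free layer, which keeps the highest intensity (white)
#' near the microchannel walls.
#'
#' Callers should denoise the frames first (median 3x3; see
#' [median_filter_stack()]) or use [measure_cfl_stack()] which does both.
#'
#' @param stack an [image_stack].
#' @return a `projection_image` on the native intensity scale.
#' @export
max_intensity_image <- function(stack) {
  if (n_frames(stack) < 1L) stop("empty stack")
  out <- if (stack$mode == "brightfield") {
    structure(Reduce(pmin, stack$frames), method = "max_cell_signal")
  } else {
    structure(Reduce(pmax, stack$frames), method = "max_cell_signal")
  }
  structure(out, class = c("projection_image", "matrix"),
            mode = stack$mode)
}

#' Binarize an extreme-intensity projection into the cell-core mask
#'
#' Foreground is the cell-traversed core region. On a brightfield projection
#' the core is dark, so foreground is `pixels <= level`; on a fluorescence
#' projection the core is bright (`pixels > level`). The level is computed
#' with [iterative_threshold()] when `level = "auto"`.
#'
#' @param projection a `projection_image` from [max_intensity_image()] (must
#'   carry its `mode` attribute, or pass `mode`).
#' @param level numeric threshold or `"auto"`.
#' @param mode `"brightfield"` or `"fluorescence"`; defaults to the
#'   projection's `mode` attribute.
#' @return logical core mask.
#' @export
cfl_binarize <- function(projection, level = "auto", mode = NULL) {
  mode <- mode %||% attr(projection, "mode") %||% "brightfield"
  m <- unclass(projection)
  attributes(m) <- list(dim = dim(projection))
  if (identical(level, "auto")) level <- iterative_threshold(m)$level
  if (mode == "brightfield") m <= level else m > level
}

#' Wall-referenced cell-free layer thickness per column
#'
#' For each column of the wall span, scans inward from the wall row (downward
#' for an upper wall, upward for a lower wall) to the first core pixel; the
#' CFL thickness at that column is the scanned distance in pixels,
#' `thickness_px(x) = first_core_row(x) - wall_y(x)` (mirrored for the lower
#' wall). Columns with no core pixel on the scan path are reported as missing
#' (`NA`), never as 0.
#'
#' @param core_mask logical matrix from [cfl_binarize()].
#' @param wall a [wall_model] whose span lies within the mask width.
#' @param pixel_size micrometres per pixel.
#' @return a `cfl_profile` data frame: `column, thickness_px, thickness_um`.
#' @export
measure_cfl <- function(core_mask, wall, pixel_size = 1) {
  H <- nrow(core_mask); W <- ncol(core_mask)
  if (min(wall$columns) < 0L || max(wall$columns) >= W)
    stop("wall span outside the mask width")
  if (min(wall$wall_y) < 0 || max(wall$wall_y) > H - 1)
    stop("wall rows outside the frame")
  thickness <- rep(NA_real_, length(wall$columns))
  for (k in seq_along(wall$columns)) {
    col <- core_mask[, wall$columns[k] + 1L]
    w <- wall$wall_y[k]
    if (wall$side == "upper") {
      rows <- which(col) - 1L                  # 0-based core rows
      rows <- rows[rows >= w]
      if (length(rows) > 0L) thickness[k] <- min(rows) - w
    } else {
      rows <- which(col) - 1L
      rows <- rows[rows <= w]
      if (length(rows) > 0L) thickness[k] <- w - max(rows)
    }
  }
  structure(data.frame(column = wall$columns, thickness_px = thickness,
                       thickness_um = thickness * pixel_size),
            class = c("cfl_profile", "data.frame"))
}

#' Region-wise summaries of a CFL profile
#'
#' Mean and sample (n-1) standard deviation of the per-column thickness over
#' labelled column windows (the measurement regions, e.g. A..F along a
#' bifurcation/confluence). Missing columns are excluded; a region whose
#' columns are all missing is reported as missing.
#'
#' @param profile a `cfl_profile`.
#' @param regions data frame with columns `region, x_start, x_end`
#'   (inclusive column windows inside the profile span, non-overlapping).
#' @return data frame `region, x_start, x_end, n, mean_um, sd_um`.
#' @export
summarize_regions <- function(profile, regions) {
  regions <- as.data.frame(regions)
  if (nrow(regions) == 0L) stop("empty region table")
  if (any(regions$x_start > regions$x_end)) stop("region with x_start > x_end")
  span <- range(profile$column)
  if (any(regions$x_start < span[1]) || any(regions$x_end > span[2]))
    stop("region window outside the profile span")
  o <- order(regions$x_start)
  if (any(regions$x_start[o][-1] <= regions$x_end[o][-nrow(regions)]))
    stop("region windows overlap")
  res <- lapply(seq_len(nrow(regions)), function(i) {
    sel <- profile$column >= regions$x_start[i] &
      profile$column <= regions$x_end[i]
    v <- profile$thickness_um[sel]
    v <- v[!is.na(v)]
    data.frame(region = regions$region[i], x_start = regions$x_start[i],
               x_end = regions$x_end[i], n = length(v),
               mean_um = if (length(v)) mean(v) else NA_real_,
               sd_um = if (length(v) > 1L) sd(v) else
                 if (length(v) == 1L) 0 else NA_real_)
  })
  do.call(rbind, res)
}

#' Compare two CFL profiles region by region
#'
#' Computes, per region, the difference of mean thickness (first minus
#' second), and over the shared columns where both profiles are present, a
#' Spearman rank correlation of per-column thickness. Used to compare the
#' automatic measurement against a manual/semi-automatic baseline.
#'
#' @param profile_a,profile_b two `cfl_profile`s on the same column span.
#' @param regions region table as in [summarize_regions()].
#' @return list with `regions` (data frame `region, mean_a_um, mean_b_um,
#'   delta_um`) and `rank_correlation`.
#' @export
compare_cfl_methods <- function(profile_a, profile_b, regions) {
  if (length(intersect(profile_a$column, profile_b$column)) == 0L)
    stop("profiles have disjoint column spans")
  sa <- summarize_regions(profile_a, regions)
  sb <- summarize_regions(profile_b, regions)
  reg <- data.frame(region = sa$region, mean_a_um = sa$mean_um,
                    mean_b_um = sb$mean_um,
                    delta_um = sa$mean_um - sb$mean_um)
  shared <- intersect(profile_a$column, profile_b$column)
  va <- profile_a$thickness_um[match(shared, profile_a$column)]
  vb <- profile_b$thickness_um[match(shared, profile_b$column)]
  ok <- !is.na(va) & !is.na(vb)
  rc <- if (sum(ok) >= 2L) cor(va[ok], vb[ok], method = "spearman")
        else NA_real_
  list(regions = reg, rank_correlation = rc)
}

#' @export
print.cfl_profile <- function(x, ...) {
  ok <- !is.na(x$thickness_px)
  cat(sprintf("<cfl_profile> %d column(s), %d measured, %d missing\n",
              nrow(x), sum(ok), sum(!ok)))
  if (any(ok))
    cat(sprintf("  thickness: mean %.2f px (%.2f um), range [%g, %g] px\n",
                mean(x$thickness_px[ok]), mean(x$thickness_um[ok]),
                min(x$thickness_px[ok]), max(x$thickness_px[ok])))
  invisible(x)
}

#' Plot a CFL thickness profile
#' @param x a `cfl_profile`.
#' @param ... passed to [plot()].
#' @export
plot.cfl_profile <- function(x, ...) {
  plot(x$column, x$thickness_um, type = "l", xlab = "column x [px]",
       ylab = "CFL thickness [um]", ...)
  invisible(x)
}
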