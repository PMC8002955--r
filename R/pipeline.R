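#' Automatic cell tracking pipeline
#'
#' Runs the full detection/tracking chain on a stack: optional ROI crop,
#' polarity normalization (cells bright), median denoising (5x5 by default),
#' per-frame automatic intermeans threshold (or a user-supplied level),
#' binarization, connected-component extraction with area filtering,
#' greedy nearest-pair trajectory linking, and short-track elimination.
#'
#' @param stack an [image_stack].
#' @param roi optional [rect] to crop to (track coordinates are then relative
#'   to the ROI).
#' @param median_kernel odd median kernel size (1 disables).
#' @param threshold `"auto"` (per-frame intermeans iteration) or a numeric
#'   level applied to every frame.
#' @param area_min,area_max inclusive blob area bounds in pixels.
#' @param connectivity 4 or 8.
#' @param link_max_displacement linking gate in pixels.
#' @param min_track_length minimum surviving track length in frames.
#' @param pad median-filter border handling, `"replicate"` or `"zero"`.
#' @return a `cell_tracks` data frame with attributes `levels` (per-frame
#'   thresholds) and `n_blobs` (per-frame surviving blob counts).
#' @export
track_cells <- function(stack, roi = NULL, median_kernel = 5L,
                        threshold = "auto", area_min = 5, area_max = Inf,
                        connectivity = 8L, link_max_displacement = 10,
                        min_track_length = 10L,
                        pad = c("replicate", "zero")) {
  pad <- match.arg(pad)
  if (!is.null(roi)) stack <- crop_stack(stack, roi)
  maxv <- max_intensity(stack)
  levels <- numeric(n_frames(stack))
  blobs_per_frame <- vector("list", n_frames(stack))
  for (i in seq_len(n_frames(stack))) {
    f <- normalize_polarity(stack$frames[[i]], stack$mode, maxv)
    if (median_kernel > 1L) f <- median_filter(f, median_kernel, pad)
    lev <- if (identical(threshold, "auto")) iterative_threshold(f)$level
           else threshold
    levels[i] <- lev
    blobs <- extract_blobs(binarize(f, lev), connectivity,
                           frame_index = i - 1L)
    blobs_per_frame[[i]] <- filter_by_area(blobs, area_min, area_max)
  }
  tracks <- link_tracks(blobs_per_frame, link_max_displacement)
  tracks <- filter_by_track_length(tracks, min_track_length)
  attr(tracks, "levels") <- levels
  attr(tracks, "n_blobs") <- vapply(blobs_per_frame, nrow, integer(1))
  tracks
}

#' Automatic cell-free layer measurement pipeline
#'
#' Runs the full CFL chain on a brightfield stack: per-frame median
#' denoising (3x3 by default), temporal extreme-intensity projection,
#' binarization into the cell-core mask, and wall-referenced per-column
#' thickness measurement, with optional region summaries.
#'
#' @param stack an [image_stack] (brightfield).
#' @param wall a [wall_model] (the user-selected channel wall).
#' @param median_kernel odd median kernel size (1 disables).
#' @param threshold `"auto"` or a numeric level for [cfl_binarize()].
#' @param regions optional region table (`region, x_start, x_end`) for
#'   [summarize_regions()].
#' @param pixel_size micrometres per pixel; defaults to the stack's.
#' @return list with `profile` (a `cfl_profile`), `level` (threshold used),
#'   `projection` (the extreme-intensity image) and, when `regions` is
#'   given, `regions` (the summary table).
#' @export
measure_cfl_stack <- function(stack, wall, median_kernel = 3L,
                              threshold = "auto", regions = NULL,
                              pixel_size = NULL) {
  pixel_size <- pixel_size %||% stack$pixel_size
  if (median_kernel > 1L)
    stack <- median_filter_stack(stack, median_kernel)
  proj <- max_intensity_image(stack)
  level <- if (identical(threshold, "auto"))
    iterative_threshold(matrix(as.numeric(proj), nrow(proj)))$level
  else threshold
  core <- cfl_binarize(proj, level)
  profile <- measure_cfl(core, wall, pixel_size)
  out <- list(profile = profile, level = level, projection = proj)
  if (!is.null(regions)) out$regions <- summarize_regions(profile, regions)
  out
}

#' Score detected tracks against ground truth
#'
#' Matches every ground-truth position to the nearest detected point of the
#' same frame within `match_radius`, and scores identity preservation by the
#' majority detected track covering each truth trajectory.
#'
#' @param tracks detected `cell_tracks`.
#' @param truth_tracks ground-truth tracks (`track_id, frame, x, y`).
#' @param match_radius maximum truth-to-detection distance in pixels.
#' @return list: `recall` (fraction of truth positions matched),
#'   `identity_recall` (fraction matched by each truth track's majority
#'   detected track), `mean_error_px` (mean matched distance),
#'   `max_error_px`, `tracks_per_truth` (mean number of distinct detected
#'   tracks per truth trajectory), `n_truth` (total truth positions).
#' @export
evaluate_tracking <- function(tracks, truth_tracks, match_radius = 2) {
  truth <- as.data.frame(truth_tracks)
  det <- as.data.frame(tracks)
  n <- nrow(truth)
  matched_id <- rep(NA_integer_, n)
  matched_d <- rep(NA_real_, n)
  det_by_frame <- split(det, det$frame)
  for (i in seq_len(n)) {
    cand <- det_by_frame[[as.character(truth$frame[i])]]
    if (is.null(cand) || nrow(cand) == 0L) next
    d2 <- (cand$x - truth$x[i])^2 + (cand$y - truth$y[i])^2
    j <- which.min(d2)
    if (d2[j] <= match_radius^2) {
      matched_id[i] <- cand$track_id[j]
      matched_d[i] <- sqrt(d2[j])
    }
  }
  ok <- !is.na(matched_id)
  id_ok <- logical(n)
  per_truth <- split(seq_len(n), truth$track_id)
  n_ids <- vapply(per_truth, function(idx) {
    ids <- matched_id[idx]
    ids <- ids[!is.na(ids)]
    if (length(ids) == 0L) return(0L)
    maj <- as.integer(names(sort(table(ids), decreasing = TRUE))[1])
    id_ok[idx] <<- !is.na(matched_id[idx]) & matched_id[idx] == maj
    length(unique(ids))
  }, integer(1))
  list(recall = mean(ok),
       identity_recall = mean(id_ok),
       mean_error_px = if (any(ok)) mean(matched_d[ok]) else NA_real_,
       max_error_px = if (any(ok)) max(matched_d[ok]) else NA_real_,
       tracks_per_truth = mean(n_ids),
       n_truth = n)
}
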