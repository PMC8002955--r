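#' Extract connected components and their properties
#'
#' Labels the foreground of a binary frame (4- or 8-connectivity) and
#' measures, per component: area (pixel count), centroid (arithmetic mean of
#' member pixel coordinates, 0-based `x` = column / `y` = row) and bounding
#' box. This is the regionprops step of the tracking pipeline: each connected
#' component is one candidate cell.
#'
#' @param binary logical (or 0/1) matrix, TRUE = foreground.
#' @param connectivity 4 or 8 (default 8: diagonal touches merge, fewer and
#'   larger components, appropriate for compact cell images).
#' @param frame_index optional 0-based frame index stored in the result.
#' @return data frame with one row per blob: `label, area, x, y, bbox_x0,
#'   bbox_y0, bbox_w, bbox_h` (and `frame` when `frame_index` is given).
#' @export
extract_blobs <- function(binary, connectivity = 8L, frame_index = NULL) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  mask <- matrix(as.logical(binary), nrow(binary), ncol(binary))
  lab <- label_components_cpp(mask, as.integer(connectivity))
  idx <- which(lab > 0L)
  if (length(idx) == 0L) {
    out <- data.frame(label = integer(), area = integer(), x = numeric(),
                      y = numeric(), bbox_x0 = integer(), bbox_y0 = integer(),
                      bbox_w = integer(), bbox_h = integer())
    if (!is.null(frame_index)) out$frame <- integer()
    return(out)
  }
  l <- lab[idx]
  r0 <- (idx - 1L) %% nrow(mask)        # 0-based row
  c0 <- (idx - 1L) %/% nrow(mask)       # 0-based col
  area <- tabulate(l)
  keep <- which(area > 0L)
  sx <- rowsum(as.numeric(c0), l)[, 1]
  sy <- rowsum(as.numeric(r0), l)[, 1]
  xmin <- tapply(c0, l, min); xmax <- tapply(c0, l, max)
  ymin <- tapply(r0, l, min); ymax <- tapply(r0, l, max)
  out <- data.frame(label = keep, area = area[keep],
                    x = sx / area[keep], y = sy / area[keep],
                    bbox_x0 = as.integer(xmin), bbox_y0 = as.integer(ymin),
                    bbox_w = as.integer(xmax - xmin + 1L),
                    bbox_h = as.integer(ymax - ymin + 1L))
  rownames(out) <- NULL
  if (!is.null(frame_index)) out$frame <- as.integer(frame_index)
  out
}

#' Filter blobs by area
#'
#' Keeps blobs whose area lies in the inclusive interval
#' `[area_min, area_max]`, preserving order. Removes detections that are not
#' red blood cells (platelets below, white blood cells above the RBC size
#' range).
#'
#' @param blobs a blob table from [extract_blobs()].
#' @param area_min,area_max inclusive bounds in pixels.
#' @return the filtered blob table.
#' @export
filter_by_area <- function(blobs, area_min = 1, area_max = Inf) {
  if (area_min > area_max) stop("area_min must be <= area_max")
  blobs[blobs$area >= area_min & blobs$area <= area_max, , drop = FALSE]
}

#' Link per-frame detections into trajectories
#'
#' Greedy globally-nearest-pair assignment per frame transition: among all
#' (active track, new blob) pairs, the pair with the smallest Euclidean
#' centroid distance is matched first, repeatedly, while the distance does
#' not exceed `link_max_displacement`. Unmatched blobs start new tracks;
#' unmatched tracks terminate (no gap closing — a cell lost for one frame
#' starts a new track). Distance ties are broken by lower track id, then
#' lower blob label, which makes the result invariant to per-frame blob
#' ordering.
#'
#' @param blobs_per_frame list of blob tables, one per consecutive frame
#'   (element i = frame index i - 1; empty frames allowed).
#' @param link_max_displacement gate: maximum centroid displacement in pixels
#'   between consecutive frames.
#' @return a `cell_tracks` data frame with columns `track_id, frame, x, y`,
#'   sorted by `(track_id, frame)`; frame indices are 0-based.
#' @export
link_tracks <- function(blobs_per_frame, link_max_displacement) {
  gate <- link_max_displacement
  if (!is.numeric(gate) || gate < 0) stop("link_max_displacement must be >= 0")
  n <- length(blobs_per_frame)
  rows <- list()            # accumulated (track_id, frame, x, y)
  active <- data.frame(track_id = integer(), x = numeric(), y = numeric())
  next_id <- 0L
  for (f in seq_len(n)) {
    blobs <- blobs_per_frame[[f]]
    nb <- if (is.null(blobs)) 0L else nrow(blobs)
    matched_track <- integer(0)
    matched_blob <- integer(0)
    if (nrow(active) > 0L && nb > 0L) {
      # all candidate pairs within the gate, globally nearest first
      d <- outer(active$x, blobs$x, "-")^2 + outer(active$y, blobs$y, "-")^2
      cand <- which(d <= gate^2, arr.ind = TRUE)
      if (nrow(cand) > 0L) {
        dist <- sqrt(d[cand])
        ord <- order(dist, active$track_id[cand[, 1]], blobs$label[cand[, 2]])
        used_t <- logical(nrow(active)); used_b <- logical(nb)
        for (k in ord) {
          ti <- cand[k, 1]; bi <- cand[k, 2]
          if (!used_t[ti] && !used_b[bi]) {
            used_t[ti] <- TRUE; used_b[bi] <- TRUE
            matched_track <- c(matched_track, ti)
            matched_blob <- c(matched_blob, bi)
          }
        }
      }
    }
    new_active <- data.frame(track_id = integer(nb), x = numeric(nb),
                             y = numeric(nb))
    if (nb > 0L) {
      ids <- integer(nb)
      ids[matched_blob] <- active$track_id[matched_track]
      unmatched <- setdiff(seq_len(nb), matched_blob)
      # new tracks in blob-label order
      unmatched <- unmatched[order(blobs$label[unmatched])]
      if (length(unmatched) > 0L) {
        ids[unmatched] <- next_id + seq_along(unmatched) - 1L
        next_id <- next_id + length(unmatched)
      }
      rows[[f]] <- data.frame(track_id = ids, frame = f - 1L,
                              x = blobs$x, y = blobs$y)
      new_active$track_id <- ids
      new_active$x <- blobs$x
      new_active$y <- blobs$y
    }
    active <- new_active
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(track_id = integer(), frame = integer(),
               x = numeric(), y = numeric())
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cell_tracks", "data.frame"))
}

#' Drop short trajectories
#'
#' Keeps tracks with at least `min_track_length` points. Objects visible in
#' only a handful of frames carry too little information to be analyzed; the
#' default cutoff of 10 positions reflects that a track of about ten points
#' is the lower limit of a usable trajectory.
#'
#' @param tracks a `cell_tracks` data frame.
#' @param min_track_length minimum number of points (inclusive, >= 1).
#' @return the filtered `cell_tracks` data frame.
#' @export
filter_by_track_length <- function(tracks, min_track_length = 10L) {
  if (min_track_length < 1L) stop("min_track_length must be >= 1")
  if (nrow(tracks) == 0L) return(tracks)
  len <- table(tracks$track_id)
  keep <- names(len)[len >= min_track_length]
  out <- tracks[as.character(tracks$track_id) %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cell_tracks", "data.frame"))
}

#' Time-averaged mean squared displacement of one track
#'
#' `MSD(tau) = mean over t of [(x(t+tau)-x(t))^2 + (y(t+tau)-y(t))^2] *
#' pixel_size^2`, averaged over every pair of points whose frame indices
#' differ by exactly `tau`, for `tau = 1 .. span - 1` frames.
#'
#' @param track data frame with columns `frame, x, y` for a single track
#'   (pixel coordinates).
#' @param pixel_size micrometres per pixel.
#' @return data frame `lag` (frames), `msd` (um^2).
#' @export
track_msd <- function(track, pixel_size = 1) {
  track <- as.data.frame(track)
  if (nrow(track) < 2L) stop("track must have at least 2 points")
  o <- order(track$frame)
  fr <- track$frame[o]; x <- track$x[o]; y <- track$y[o]
  span <- max(fr) - min(fr)
  lags <- seq_len(span)
  msd <- vapply(lags, function(tau) {
    i <- match(fr + tau, fr)
    ok <- !is.na(i)
    if (!any(ok)) return(NA_real_)
    mean((x[i[ok]] - x[ok])^2 + (y[i[ok]] - y[ok])^2) * pixel_size^2
  }, numeric(1))
  out <- data.frame(lag = lags, msd = msd)
  out[!is.na(out$msd), , drop = FALSE]
}

#' Radial (lateral) dispersion of a set of tracks
#'
#' The wall-normal dispersion coefficient
#' `Dyy(t) = mean over tracks of (y(t) - y(0))^2 * pixel_size^2 /
#' (2 * t * frame_interval)`, with `t` counted in frames from each track's
#' start. Characterizes how fast cells spread across the channel.
#'
#' @param tracks a `cell_tracks` data frame (>= 1 track of length >= 2).
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds per frame.
#' @return data frame `time` (s), `dyy` (um^2/s), plus `n_tracks` averaged at
#'   each time point.
#' @export
radial_dispersion <- function(tracks, pixel_size = 1, frame_interval = 1) {
  tracks <- as.data.frame(tracks)
  if (nrow(tracks) == 0L) stop("no tracks")
  by_id <- split(tracks, tracks$track_id)
  by_id <- Filter(function(d) nrow(d) >= 2L, by_id)
  if (length(by_id) == 0L) stop("no track of length >= 2")
  max_t <- max(vapply(by_id, function(d) max(d$frame) - min(d$frame),
                      numeric(1)))
  steps <- seq_len(max_t)
  vals <- lapply(by_id, function(d) {
    o <- order(d$frame)
    fr <- d$frame[o] - min(d$frame)   # relative frame from track start
    y <- d$y[o]
    i <- match(steps, fr)
    (y[i] - y[1])^2                    # NA where the track has no point
  })
  m <- do.call(cbind, vals)
  dyy <- rowMeans(m, na.rm = TRUE) * pixel_size^2 /
    (2 * steps * frame_interval)
  n_tracks <- rowSums(!is.na(m))
  keep <- n_tracks > 0
  data.frame(time = steps[keep] * frame_interval, dyy = dyy[keep],
             n_tracks = n_tracks[keep])
}

#' @export
print.cell_tracks <- function(x, ...) {
  nt <- length(unique(x$track_id))
  cat(sprintf("<cell_tracks> %d point(s) in %d track(s)\n", nrow(x), nt))
  if (nrow(x) > 0L) {
    len <- table(x$track_id)
    cat(sprintf("  track length: min %d, median %s, max %d; frames %d..%d\n",
                min(len), format(median(as.numeric(len))), max(len),
                min(x$frame), max(x$frame)))
  }
  invisible(x)
}

#' Plot trajectories
#' @param x a `cell_tracks` data frame.
#' @param ... passed to [plot()].
#' @export
plot.cell_tracks <- function(x, ...) {
  if (nrow(x) == 0L) {
    plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "x [px]", ylab = "y [px]")
    return(invisible(x))
  }
  plot(NA, xlim = range(x$x), ylim = rev(range(x$y)),
       xlab = "x [px]", ylab = "y [px]", ...)
  for (d in split(x, x$track_id)) lines(d$x, d$y, col = d$track_id[1] %% 8 + 1)
  invisible(x)
}
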