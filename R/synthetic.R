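#' Simulate a fluorescence capillary sequence with ground-truth tracks
#'
#' Generates a time-lapse stack emulating labeled red blood cells flowing in
#' a horizontally mounted circular glass capillary imaged at its center
#' plane: bright anisotropic Gaussian cells (sigma = cell_radius / 2, soft
#' edges with sub-pixel centroids) on a dark background, advected along x by
#' a plug or Poiseuille profile `v(y) = v_max * (1 - (2 (y - y_c) /
#' channel_width)^2)`, plus optional Gaussian camera noise, quantized to the
#' integer intensity grid.
#'
#' Cells are laid out in constant-y lanes whose spacing exceeds the
#' thresholded blob footprint, so detected blobs never merge — the synthetic
#' analogue of working at a deliberately low (12%) hematocrit to keep
#' tracking errors down. The x spawn window is sized so every cell stays
#' fully inside the frame for the whole sequence, and the ground truth
#' therefore covers every frame of every cell.
#'
#' @param n_cells number of cells in view.
#' @param n_frames number of frames.
#' @param width,height frame size in pixels.
#' @param pixel_size micrometres per pixel (0.45 um/px places the 100 um
#'   capillary across ~222 rows of the 480-row frame).
#' @param frame_interval seconds per frame (0.01 s = 100 frames/s).
#' @param channel_width_um capillary inner diameter in micrometres.
#' @param cell_radius_px cell radius in pixels (Gaussian sigma is half this).
#' @param eccentricity ratio sigma_x / sigma_y (> 1 elongates along flow).
#' @param v_max centerline velocity, pixels per frame.
#' @param velocity_profile `"poiseuille"` or `"plug"`.
#' @param background_level,cell_contrast background intensity and peak cell
#'   amplitude above background, intensity units.
#' @param noise_sigma Gaussian noise standard deviation, intensity units.
#' @param bit_depth 8 or 16.
#' @param seed integer random seed; identical seeds give bit-identical stacks.
#' @return list with `stack` (an [image_stack]) and `truth`, a list holding
#'   `tracks` (data frame `track_id, frame, x, y`, 0-based, sub-pixel) and
#'   the channel geometry (`y_center`, `channel_width_px`).
#' @export
simulate_capillary <- function(n_cells = 20L, n_frames = 100L,
                               width = 640L, height = 480L,
                               pixel_size = 0.45, frame_interval = 0.01,
                               channel_width_um = 100,
                               cell_radius_px = 9, eccentricity = 1,
                               v_max = 4,
                               velocity_profile = c("poiseuille", "plug"),
                               background_level = 20, cell_contrast = 150,
                               noise_sigma = 0, bit_depth = 8L,
                               seed = 1L) {
  velocity_profile <- match.arg(velocity_profile)
  if (v_max <= 0) stop("v_max must be > 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  set.seed(seed)
  maxv <- 2^bit_depth - 1
  sig_y <- cell_radius_px / 2
  sig_x <- sig_y * eccentricity
  chan_w <- channel_width_um / pixel_size
  y_c <- (height - 1) / 2

  # lane layout: vertical gap > 2x the thresholded blob footprint
  lane_gap <- ceiling(5 * sig_y)
  margin_y <- ceiling(3 * sig_y)
  y_lo <- y_c - chan_w / 2 + margin_y
  y_hi <- y_c + chan_w / 2 - margin_y
  if (y_lo < margin_y) y_lo <- margin_y
  if (y_hi > height - 1 - margin_y) y_hi <- height - 1 - margin_y
  lane_y <- seq(y_lo, y_hi, by = lane_gap)
  # x spawn window keeps every cell in-frame for the full sequence
  margin_x <- ceiling(3.5 * sig_x)
  min_dx <- ceiling(6 * sig_x)
  x_last <- width - 1 - margin_x - v_max * (n_frames - 1)
  if (x_last <= margin_x)
    stop("invalid geometry: v_max * n_frames leaves no spawn window")
  slots_per_lane <- floor((x_last - margin_x) / min_dx) + 1
  if (n_cells > length(lane_y) * slots_per_lane)
    stop("invalid geometry: too many cells for non-overlapping lane layout")

  cells <- data.frame(x0 = numeric(0), y0 = numeric(0))
  if (n_cells > 0L) {
    lane_of <- rep(sample(seq_along(lane_y)), length.out = n_cells)
    x0 <- numeric(n_cells); y0 <- numeric(n_cells)
    for (ln in unique(lane_of)) {
      idx <- which(lane_of == ln)
      slots <- sample(seq_len(slots_per_lane), length(idx))
      x0[idx] <- margin_x + (slots - 1) * min_dx + runif(length(idx), 0, 1)
      y0[idx] <- lane_y[ln] + runif(length(idx), -1.5, 1.5)
    }
    cells <- data.frame(x0 = x0, y0 = y0)
  }
  v <- if (nrow(cells) == 0L) numeric(0)
  else if (velocity_profile == "plug") rep(v_max, n_cells)
  else v_max * (1 - (2 * (cells$y0 - y_c) / chan_w)^2)

  win <- ceiling(3.5 * max(sig_x, sig_y))
  frames <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    f <- matrix(background_level, height, width)
    if (n_cells > 0L) {
      cx <- cells$x0 + v * (t - 1)
      cy <- cells$y0
      for (i in seq_len(n_cells)) {
        rows <- max(1, floor(cy[i] + 1 - win)):min(height, ceiling(cy[i] + 1 + win))
        cols <- max(1, floor(cx[i] + 1 - win)):min(width, ceiling(cx[i] + 1 + win))
        gy <- exp(-((rows - 1 - cy[i])^2) / (2 * sig_y^2))
        gx <- exp(-((cols - 1 - cx[i])^2) / (2 * sig_x^2))
        f[rows, cols] <- f[rows, cols] + cell_contrast * outer(gy, gx)
      }
      truth[[t]] <- data.frame(track_id = seq_len(n_cells) - 1L,
                               frame = t - 1L, x = cx, y = cy)
    }
    if (noise_sigma > 0)
      f <- f + matrix(rnorm(height * width, 0, noise_sigma), height, width)
    frames[[t]] <- pmin(pmax(round(f), 0), maxv)
  }
  tracks <- if (n_cells > 0L) do.call(rbind, truth) else
    data.frame(track_id = integer(), frame = integer(),
               x = numeric(), y = numeric())
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  list(stack = image_stack(frames, bit_depth = bit_depth,
                           pixel_size = pixel_size,
                           frame_interval = frame_interval,
                           mode = "fluorescence"),
       truth = list(tracks = structure(tracks,
                                       class = c("cell_tracks", "data.frame")),
                    y_center = y_c, channel_width_px = chan_w,
                    v = v, velocity_profile = velocity_profile))
}

#' Simulate a brightfield channel sequence with a known cell-free layer
#'
#' Generates a brightfield stack of a horizontally oriented microchannel:
#' dark Gaussian cells on a bright background, confined to the cell-occupied
#' core band `[upper_wall + cfl_true(x), lower_wall - cfl_true(x)]` — the
#' band edge is the ground-truth CFL boundary, since the plasma layer is by
#' definition strictly cell free. Cells ride x-periodic lanes with random
#' phases (recycled across the image edge), advected by a plug profile (the
#' core of a concentrated suspension moves with a blunted, plug-like
#' profile), so that over the sequence every core pixel is traversed and the
#' temporal extreme projection fills the core.
#'
#' `wall_upper`/`wall_lower` and `cfl_true` may be scalars (straight
#' channel) or per-column vectors of length `width` (e.g. diverging /
#' converging walls approximating a bifurcation-confluence geometry, or a
#' spatially varying CFL).
#'
#' @param n_frames number of frames.
#' @param width,height frame size in pixels.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds per frame (0.005 s = 200 frames/s).
#' @param wall_upper,wall_lower wall row coordinates (0-based), scalar or
#'   per-column.
#' @param cfl_true true CFL thickness in pixels, scalar or per-column;
#'   must leave a non-empty core everywhere.
#' @param cell_radius_px cell radius in pixels (Gaussian sigma is half this).
#' @param lane_spacing_px vertical spacing of cell lanes (small enough that
#'   the rendered core is contiguous).
#' @param cell_spacing_px horizontal spacing of cells within a lane.
#' @param v_max advection speed, pixels per frame.
#' @param background_level,cell_level background and cell-interior
#'   intensities (cells darker than background).
#' @param noise_sigma Gaussian noise standard deviation, intensity units.
#' @param bit_depth 8 or 16.
#' @param seed integer random seed.
#' @return list with `stack` (an [image_stack]) and `truth`: `cfl` (data
#'   frame `column, thickness_px` for the upper wall), `wall_upper`,
#'   `wall_lower` (per-column rows).
#' @export
simulate_cfl_channel <- function(n_frames = 200L, width = 800L, height = 600L,
                                 pixel_size = 1, frame_interval = 0.005,
                                 wall_upper = 150, wall_lower = 449,
                                 cfl_true = 15,
                                 cell_radius_px = 8, lane_spacing_px = 4,
                                 cell_spacing_px = 24, v_max = 2,
                                 background_level = 220, cell_level = 40,
                                 noise_sigma = 0, bit_depth = 8L,
                                 seed = 1L) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  set.seed(seed)
  maxv <- 2^bit_depth - 1
  sig <- cell_radius_px / 2
  contrast <- background_level - cell_level
  up <- rep_len(wall_upper, width)
  lo <- rep_len(wall_lower, width)
  cfl <- rep_len(cfl_true, width)
  if (any(cfl < 0)) stop("cfl_true must be >= 0")
  core_top <- up + cfl
  core_bot <- lo - cfl
  if (any(core_top > core_bot))
    stop("cfl_true exceeds half the channel height")

  # cell-occupied band, one 0/1 column mask per x (0-based rows)
  rows0 <- 0:(height - 1)
  band <- vapply(seq_len(width), function(j)
    as.numeric(rows0 >= core_top[j] & rows0 <= core_bot[j]),
    numeric(height))

  # lanes span the widest possible core extent; clipping trims per column
  lane_y <- seq(min(core_top), max(core_bot), by = lane_spacing_px)
  phase <- runif(length(lane_y), 0, cell_spacing_px)
  n_per_lane <- ceiling(width / cell_spacing_px) + 1L
  win <- ceiling(3 * sig)
  cols0 <- 0:(width - 1)

  frames <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    dark <- matrix(0, height, width)
    for (ln in seq_along(lane_y)) {
      # periodic comb of cell centres for this lane at this time
      gx <- numeric(width)
      centers <- (phase[ln] + v_max * (t - 1) +
                    (seq_len(n_per_lane) - 1L) * cell_spacing_px) %%
        (n_per_lane * cell_spacing_px)
      centers <- centers[centers < width + win]
      for (cx in centers) {
        jj <- max(1, floor(cx + 1 - win)):min(width, ceiling(cx + 1 + win))
        gx[jj] <- gx[jj] + exp(-((jj - 1 - cx)^2) / (2 * sig^2))
      }
      rows <- max(1, floor(lane_y[ln] + 1 - win)):
        min(height, ceiling(lane_y[ln] + 1 + win))
      gy <- exp(-((rows - 1 - lane_y[ln])^2) / (2 * sig^2))
      dark[rows, ] <- dark[rows, ] + outer(gy, gx)
    }
    f <- background_level - contrast * pmin(dark, 1) * band
    if (noise_sigma > 0)
      f <- f + matrix(rnorm(height * width, 0, noise_sigma), height, width)
    frames[[t]] <- pmin(pmax(round(f), 0), maxv)
  }
  list(stack = image_stack(frames, bit_depth = bit_depth,
                           pixel_size = pixel_size,
                           frame_interval = frame_interval,
                           mode = "brightfield"),
       truth = list(cfl = data.frame(column = cols0, thickness_px = cfl),
                    wall_upper = up, wall_lower = lo))
}
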