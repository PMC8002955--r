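test_that("capillary scenes are deterministic and respect the velocity law", {
  a <- small_capillary(seed = 9, noise_sigma = 6)
  b <- small_capillary(seed = 9, noise_sigma = 6)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth$tracks, b$truth$tracks)
  # no cells, no noise: constant background
  empty <- simulate_capillary(n_cells = 0, n_frames = 3, width = 100,
                              height = 80, noise_sigma = 0, seed = 1)
  expect_true(all(vapply(empty$stack$frames,
                         function(f) all(f == f[1, 1]), logical(1))))
  # per-frame x-advance equals the Poiseuille parabola at each cell's y
  tr <- a$truth$tracks
  w <- a$truth$channel_width_px
  yc <- a$truth$y_center
  for (d in split(tr, tr$track_id)) {
    adv <- unique(round(diff(d$x), 10))
    expect_length(adv, 1L)
    v_expect <- 4 * (1 - (2 * (d$y[1] - yc) / w)^2)
    expect_equal(adv, v_expect, tolerance = 1e-9)
  }
  plug <- small_capillary(seed = 3, velocity_profile = "plug")
  for (d in split(plug$truth$tracks, plug$truth$tracks$track_id))
    expect_equal(unique(round(diff(d$x), 10)), 4)
})

test_that("a cell at a quarter-width offset advances at 0.75 v_max", {
  # direct substitution in v(y) = v_max (1 - (2 (y - yc) / w)^2)
  sim <- simulate_capillary(n_cells = 12, n_frames = 4, width = 320,
                            height = 480, v_max = 4, seed = 5)
  w <- sim$truth$channel_width_px
  yc <- sim$truth$y_center
  v_at <- function(y) 4 * (1 - (2 * (y - yc) / w)^2)
  expect_equal(v_at(yc + w / 4), 3)
  expect_equal(v_at(yc - w / 4), 3)
  expect_equal(sim$truth$v, v_at(sim$truth$tracks$y[match(
    unique(sim$truth$tracks$track_id), sim$truth$tracks$track_id)]))
})

test_that("rendering a cell at the truth centroid is recovered sub-pixel", {
  sim <- simulate_capillary(n_cells = 1, n_frames = 1, width = 120,
                            height = 120, noise_sigma = 0, seed = 13)
  f <- sim$stack$frames[[1]]
  lev <- iterative_threshold(f)$level
  b <- extract_blobs(binarize(f, lev))
  expect_equal(nrow(b), 1L)
  truth <- sim$truth$tracks
  expect_lt(sqrt((b$x - truth$x)^2 + (b$y - truth$y)^2), 0.5)
})

test_that("tracking recall degrades monotonically with noise", {
  recalls <- vapply(c(0, 12, 48), function(sig) {
    sim <- small_capillary(seed = 17, noise_sigma = sig)
    tr <- track_cells(sim$stack, link_max_displacement = 8,
                      min_track_length = 3)
    evaluate_tracking(tr, sim$truth$tracks)$recall
  }, numeric(1))
  expect_true(all(diff(recalls) <= 0))
  expect_equal(recalls[1], 1)
})

test_that("CFL scenes are deterministic with a faithful occupancy band", {
  a <- simulate_cfl_channel(n_frames = 30, width = 200, height = 150,
                            wall_upper = 30, wall_lower = 119,
                            cfl_true = 12, seed = 7)
  b <- simulate_cfl_channel(n_frames = 30, width = 200, height = 150,
                            wall_upper = 30, wall_lower = 119,
                            cfl_true = 12, seed = 7)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_equal(a$truth$cfl$thickness_px, rep(12, 200))
  # rows above wall + cfl keep background intensity in every frame
  top <- do.call(rbind, lapply(a$stack$frames, function(f) f[1:42, ]))
  expect_true(all(top == 220))
  # the full measurement chain recovers the truth
  wall <- wall_model(c(0, 199), c(30, 30))
  res <- measure_cfl_stack(a$stack, wall)
  expect_lt(mean(abs(res$profile$thickness_px - 12), na.rm = TRUE), 1)
  expect_error(simulate_cfl_channel(n_frames = 2, width = 50, height = 60,
                                    wall_upper = 10, wall_lower = 49,
                                    cfl_true = 25), "exceeds")
})

test_that("a zero cell-free layer measures approximately zero", {
  sim <- simulate_cfl_channel(n_frames = 60, width = 200, height = 120,
                              wall_upper = 20, wall_lower = 99,
                              cfl_true = 0, seed = 5)
  wall <- wall_model(c(0, 199), c(20, 20))
  res <- measure_cfl_stack(sim$stack, wall)
  expect_lt(mean(res$profile$thickness_px, na.rm = TRUE), 0.5)
})
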