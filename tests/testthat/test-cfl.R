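test_that("extreme-intensity image keeps maximum cell signal per polarity", {
  f1 <- matrix(c(0, 4, 2, 6), 2)
  f2 <- matrix(c(2, 6, 4, 8), 2)
  fl <- image_stack(list(f1, f2), mode = "fluorescence")
  expect_equal(unclass(max_intensity_image(fl)), pmax(f1, f2),
               ignore_attr = TRUE)
  bf <- image_stack(list(f1, f2), mode = "brightfield")
  expect_equal(unclass(max_intensity_image(bf)), pmin(f1, f2),
               ignore_attr = TRUE)
  # adding a frame never decreases any pixel of the cell-signal image
  fl3 <- image_stack(list(f1, f2, matrix(c(1, 9, 1, 1), 2)))
  expect_true(all(unclass(max_intensity_image(fl3)) >=
                    unclass(max_intensity_image(fl))))
})

test_that("core binarization separates a bimodal projection", {
  proj <- matrix(220, 20, 30)
  proj[8:14, ] <- 40                       # traversed core band
  s <- structure(proj, class = c("projection_image", "matrix"),
                 mode = "brightfield")
  core <- cfl_binarize(s, 130)
  expect_equal(which(rowSums(core) == 30), 8:14)
  expect_equal(sum(core), 7 * 30)
  # auto level is the intermeans solution (220 + 40) / 2
  expect_equal(iterative_threshold(proj)$level, 130)
  auto <- cfl_binarize(s, "auto")
  expect_equal(auto, core)
  expect_error(cfl_binarize(structure(matrix(220, 5, 5),
                                      class = c("projection_image", "matrix"),
                                      mode = "brightfield"), "auto"),
               "constant")
})

test_that("wall-referenced thickness tracks the core boundary per column", {
  core <- matrix(FALSE, 100, 40)
  core[21:81, ] <- TRUE                    # core rows 20..80 (0-based)
  wall <- wall_model(c(0, 39), c(0, 0), side = "upper")
  p <- measure_cfl(core, wall, pixel_size = 2)
  expect_equal(p$thickness_px, rep(20, 40))
  expect_equal(p$thickness_um, rep(40, 40))
  lower <- wall_model(c(0, 39), c(99, 99), side = "lower")
  expect_equal(measure_cfl(core, lower)$thickness_px, rep(19, 40))
  # a column with no core pixels is missing, not zero
  core[, 5] <- FALSE
  p2 <- measure_cfl(core, wall)
  expect_true(is.na(p2$thickness_px[p2$column == 4]))
  expect_equal(sum(is.na(p2$thickness_px)), 1L)
  # slanted boundary: first core row = 10 + round(0.1 x), checked per column
  sl <- matrix(FALSE, 60, 50)
  for (x in 0:49) sl[(10 + round(0.1 * x) + 1):60, x + 1] <- TRUE
  p3 <- measure_cfl(sl, wall_model(c(0, 49), c(0, 0)))
  for (x in 0:49) {
    scan <- min(which(sl[, x + 1])) - 1     # independent per-column scan
    expect_equal(p3$thickness_px[x + 1], scan)
    expect_equal(scan, 10 + round(0.1 * x))
  }
  expect_error(measure_cfl(core, wall_model(50, 0, span = c(30, 45))),
               "outside")
})

test_that("region summaries average only the measured columns", {
  prof <- structure(data.frame(column = 0:19,
                               thickness_px = rep(20, 20),
                               thickness_um = rep(20, 20)),
                    class = c("cfl_profile", "data.frame"))
  reg <- data.frame(region = c("A", "B"), x_start = c(0, 10),
                    x_end = c(9, 19))
  s <- summarize_regions(prof, reg)
  expect_equal(s$mean_um, c(20, 20))
  expect_equal(s$sd_um, c(0, 0))
  prof$thickness_um[1:10] <- c(10, 20, 10, 20, 10, 20, 10, 20, 10, 20)
  s2 <- summarize_regions(prof, reg)
  expect_equal(s2$mean_um[1], 15)
  # half of region B missing: mean over the present half only
  prof$thickness_um[11:15] <- NA
  s3 <- summarize_regions(prof, reg)
  expect_equal(s3$n[2], 5L)
  expect_equal(s3$mean_um[2], 20)
  prof$thickness_um[11:20] <- NA
  expect_true(is.na(summarize_regions(prof, reg)$mean_um[2]))
  expect_error(summarize_regions(prof, data.frame(region = "A", x_start = 5,
                                                  x_end = 25)), "outside")
  expect_error(summarize_regions(prof,
                                 data.frame(region = c("A", "B"),
                                            x_start = c(0, 5),
                                            x_end = c(9, 15))), "overlap")
})

test_that("method comparison reports deltas and rank correlation", {
  mk_prof <- function(th) structure(
    data.frame(column = seq_along(th) - 1, thickness_px = th,
               thickness_um = th),
    class = c("cfl_profile", "data.frame"))
  reg <- data.frame(region = "A", x_start = 0, x_end = 2)
  a <- mk_prof(c(1, 2, 3))
  same <- compare_cfl_methods(a, a, reg)
  expect_equal(same$regions$delta_um, 0)
  expect_equal(same$rank_correlation, 1)
  off <- compare_cfl_methods(mk_prof(c(3, 4, 5)), a, reg)
  expect_equal(off$regions$delta_um, 2)
  expect_equal(off$rank_correlation, 1)
  anti <- compare_cfl_methods(a, mk_prof(c(3, 2, 1)), reg)
  expect_equal(anti$rank_correlation, -1)
  b <- mk_prof(c(1, 2, 3)); b$column <- b$column + 100
  expect_error(compare_cfl_methods(a, b, reg), "disjoint")
})

test_that("wall polylines interpolate piecewise-linearly per column", {
  w <- wall_model(c(0, 10, 20), c(0, 10, 0))
  expect_equal(w$columns, 0:20)
  expect_equal(w$wall_y[6], 5)     # column 5, rising edge
  expect_equal(w$wall_y[16], 5)    # column 15, falling edge
  expect_equal(wall_model(7, 3, span = c(0, 4))$wall_y, rep(3, 5))
  expect_error(wall_model(c(5, 1), c(0, 0)), "non-decreasing")
})
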