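test_that("blob extraction measures area, centroid and bbox", {
  expect_equal(nrow(extract_blobs(matrix(FALSE, 5, 5))), 0L)
  m <- matrix(FALSE, 8, 10)
  m[3:5, 6:8] <- TRUE                     # 3x3 square, top-left (row 2, col 5)
  b <- extract_blobs(m)
  expect_equal(nrow(b), 1L)
  expect_equal(b$area, 9L)
  expect_equal(b$x, 6)                    # 0-based centroid (6, 3)
  expect_equal(b$y, 3)
  expect_equal(c(b$bbox_x0, b$bbox_y0, b$bbox_w, b$bbox_h), c(5L, 2L, 3L, 3L))
})

test_that("diagonal touches merge at connectivity 8 but not 4", {
  m <- matrix(FALSE, 4, 4)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_equal(nrow(extract_blobs(m, 8)), 1L)
  expect_equal(nrow(extract_blobs(m, 4)), 2L)
  expect_error(extract_blobs(m, 6), "connectivity")
})

test_that("components match a flood-fill oracle and conserve total area", {
  set.seed(41)
  for (rep in 1:15) {
    m <- matrix(runif(12 * 14) < 0.4, 12, 14)
    for (conn in c(4L, 8L)) {
      b <- extract_blobs(m, conn)
      lab <- oracle_label(m, conn)
      expect_equal(sum(b$area), sum(m))
      sig <- sort(sprintf("a=%d x=%.6f y=%.6f", b$area, b$x, b$y))
      expect_equal(sig, oracle_blob_signature(lab))
    }
  }
})

test_that("area filtering keeps the inclusive interval in order", {
  b <- data.frame(label = 1:3, area = c(3, 25, 500), x = 1:3, y = 1:3)
  expect_equal(filter_by_area(b, 10, 100)$area, 25)
  expect_equal(filter_by_area(b, 0, Inf)$area, c(3, 25, 500))
  expect_equal(filter_by_area(b, 25, 100)$area, 25)   # boundary kept
  expect_error(filter_by_area(b, 10, 5), "area_min")
})

test_that("linking follows moving blobs and respects the gate", {
  mk <- function(frames, xs, ys)
    lapply(seq_along(frames), function(i)
      data.frame(label = seq_along(xs[[i]]), area = rep(10, length(xs[[i]])),
                 x = xs[[i]], y = ys[[i]]))
  # one blob moving +2 px/frame: a single 5-point track
  bl <- mk(1:5, as.list(seq(0, 8, by = 2)), as.list(rep(3, 5)))
  tr <- link_tracks(bl, 5)
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_equal(tr$x, seq(0, 8, by = 2))
  expect_equal(tr$frame, 0:4)
  # two distant blobs: no identity swap possible through the gate
  bl2 <- mk(1:4, lapply(0:3, function(t) c(0 + t, 100 + t)),
            lapply(0:3, function(t) c(5, 5)))
  tr2 <- link_tracks(bl2, 5)
  expect_equal(length(unique(tr2$track_id)), 2L)
  for (d in split(tr2, tr2$track_id))
    expect_equal(diff(d$x), rep(1, 3))
  # blob vanishing for one frame starts a new track (no gap closing)
  bl3 <- mk(1:3, list(0, numeric(0), 0.5), list(0, numeric(0), 0.5))
  tr3 <- link_tracks(bl3, 5)
  expect_equal(length(unique(tr3$track_id)), 2L)
})

test_that("two approaching blobs link as the optimal 2x2 assignment", {
  # brute-force oracle: enumerate both assignments, take minimal total distance
  prev <- data.frame(label = 1:2, x = c(0, 4), y = c(0, 0))
  nxt <- data.frame(label = 1:2, x = c(1.5, 3.0), y = c(0, 0))
  d <- function(i, j) sqrt((prev$x[i] - nxt$x[j])^2 + (prev$y[i] - nxt$y[j])^2)
  straight <- d(1, 1) + d(2, 2)
  crossed <- d(1, 2) + d(2, 1)
  best <- if (straight <= crossed) c(1L, 2L) else c(2L, 1L)
  bl <- list(cbind(prev, area = 10), cbind(nxt, area = 10))
  tr <- link_tracks(bl, 5)
  t1 <- tr[tr$track_id == 0L, ]
  expect_equal(t1$x[2], nxt$x[best[1]])
  t2 <- tr[tr$track_id == 1L, ]
  expect_equal(t2$x[2], nxt$x[best[2]])
})

test_that("linking is invariant to per-frame blob ordering", {
  set.seed(42)
  frames <- lapply(1:6, function(t)
    data.frame(label = 1:4, area = 10,
               x = c(10, 30, 50, 70) + t + rnorm(4, 0, 0.3),
               y = rep(10, 4) + rnorm(4, 0, 0.3)))
  shuffled <- lapply(frames, function(f) {
    g <- f[sample(nrow(f)), , drop = FALSE]
    rownames(g) <- NULL
    g
  })
  a <- link_tracks(frames, 5)
  b <- link_tracks(shuffled, 5)
  key <- function(d) d[order(d$track_id, d$frame), c("frame", "x", "y")]
  expect_equal(key(a), key(b), ignore_attr = TRUE)
})

test_that("short tracks are eliminated at the inclusive cutoff", {
  tr <- do.call(rbind, lapply(c(3, 10, 50), function(len)
    data.frame(track_id = len, frame = seq_len(len) - 1, x = 0, y = 0)))
  tr <- structure(tr, class = c("cell_tracks", "data.frame"))
  kept <- filter_by_track_length(tr, 10)
  expect_equal(sort(unique(kept$track_id)), c(10, 50))
  expect_equal(filter_by_track_length(tr, 1), tr, ignore_attr = TRUE)
  empty <- tr[0, ]
  expect_equal(nrow(filter_by_track_length(empty, 5)), 0L)
  expect_error(filter_by_track_length(tr, 0), ">= 1")
})

test_that("MSD closed forms and brute-force double loop agree", {
  stat <- data.frame(frame = 0:9, x = 4, y = 7)
  expect_true(all(track_msd(stat)$msd == 0))
  v <- 3
  ball <- data.frame(frame = 0:9, x = v * (0:9), y = 2)
  m <- track_msd(ball, pixel_size = 1)
  expect_equal(m$msd, (v * m$lag)^2, tolerance = 1e-9)
  tri <- data.frame(frame = 0:1, x = c(0, 3), y = c(0, 4))
  expect_equal(track_msd(tri)$msd, 25)
  set.seed(43)
  rw <- data.frame(frame = 0:7, x = cumsum(rnorm(8)), y = cumsum(rnorm(8)))
  expect_equal(track_msd(rw, pixel_size = 0.5),
               oracle_msd(rw, pixel_size = 0.5), ignore_attr = TRUE)
  expect_error(track_msd(rw[1, ]), "2 points")
})

test_that("radial dispersion matches its definition and scaling law", {
  flat <- data.frame(track_id = rep(0:1, each = 5), frame = rep(0:4, 2),
                     x = rnorm(10), y = rep(c(3, 8), each = 5))
  expect_true(all(radial_dispersion(flat)$dyy == 0))
  one <- data.frame(track_id = 0L, frame = 0:1, x = c(0, 0), y = c(0, 2))
  expect_equal(radial_dispersion(one, 1, 1)$dyy[1], 2)   # 2^2 / (2 * 1 * 1)
  set.seed(44)
  rw <- data.frame(track_id = rep(0:2, each = 6), frame = rep(0:5, 3),
                   x = rnorm(18), y = cumsum(rnorm(18)))
  d1 <- radial_dispersion(rw, pixel_size = 1, frame_interval = 0.01)
  d2 <- radial_dispersion(rw, pixel_size = 2, frame_interval = 0.01)
  expect_equal(d2$dyy, 4 * d1$dyy)
  expect_equal(d1$time, (1:5) * 0.01)
  expect_error(radial_dispersion(rw[1, , drop = FALSE]), "length >= 2")
})
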