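# Independent brute-force oracles used to check the implementation.
# These are deliberately naive (explicit loops, BFS, closed forms) and share
# no code with the package internals.

random_frame <- function(h, w, maxv = 255) {
  matrix(sample(0:maxv, h * w, replace = TRUE), h, w)
}

# median filter by explicit neighborhood sort
oracle_median <- function(m, k, pad = "replicate") {
  r <- k %/% 2
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    v <- numeric(0)
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > H || jj < 1 || jj > W) {
        v <- c(v, if (pad == "zero") 0 else
          m[min(max(ii, 1), H), min(max(jj, 1), W)])
      } else v <- c(v, m[ii, jj])
    }
    out[i, j] <- median(sort(v))
  }
  out
}

# Sobel magnitude by explicit 3x3 convolution with edge replication
oracle_sobel <- function(m) {
  H <- nrow(m); W <- ncol(m)
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3)      # columns: left,0,right
  ky <- t(kx)
  out <- matrix(0, H, W)
  at <- function(i, j) m[min(max(i, 1), H), min(max(j, 1), W)]
  for (i in 1:H) for (j in 1:W) {
    gx <- 0; gy <- 0
    for (di in -1:1) for (dj in -1:1) {
      gx <- gx + kx[di + 2, dj + 2] * at(i + di, j + dj)
      gy <- gy + ky[di + 2, dj + 2] * at(i + di, j + dj)
    }
    out[i, j] <- sqrt(gx^2 + gy^2)
  }
  out
}

# direct iteration of the intermeans update rule
oracle_intermeans <- function(v, tol = 0.5, max_iter = 100) {
  v <- as.numeric(v)
  t_cur <- mean(v)
  for (i in seq_len(max_iter)) {
    t_new <- (mean(v[v <= t_cur]) + mean(v[v > t_cur])) / 2
    if (abs(t_new - t_cur) < tol) return(t_new)
    t_cur <- t_new
  }
  t_cur
}

# all fixed points of the intermeans map found by scanning every possible
# background/object cut of the sorted distinct values
oracle_intermeans_fixed_points <- function(v) {
  v <- as.numeric(v)
  u <- sort(unique(v))
  fps <- numeric(0)
  for (c in u[-length(u)]) {
    t_c <- (mean(v[v <= c]) + mean(v[v > c])) / 2
    # stable iff thresholding at t_c reproduces the same partition
    if (max(v[v <= t_c]) == max(v[v <= c])) fps <- c(fps, t_c)
  }
  fps
}

# connected-component labeling by BFS flood fill
oracle_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  nxt <- 0L
  for (j in 1:W) for (i in 1:H) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        ii <- p[1] + nb[k, 1]; jj <- p[2] + nb[k, 2]
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- nxt
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# per-component area/centroid summary of an oracle labeling, as a sorted
# set of strings so the comparison ignores label numbering
oracle_blob_signature <- function(lab) {
  ids <- setdiff(unique(as.vector(lab)), 0L)
  sig <- vapply(ids, function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    sprintf("a=%d x=%.6f y=%.6f", nrow(w),
            mean(w[, 2] - 1), mean(w[, 1] - 1))
  }, character(1))
  sort(sig)
}

# wand selection by BFS flood fill with tolerance
oracle_wand <- function(m, x, y, tol) {
  H <- nrow(m); W <- ncol(m)
  v0 <- m[y + 1, x + 1]
  mask <- matrix(FALSE, H, W)
  mask[y + 1, x + 1] <- TRUE
  queue <- list(c(y + 1, x + 1))
  while (length(queue) > 0) {
    p <- queue[[1]]; queue <- queue[-1]
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- p[1] + di; jj <- p[2] + dj
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
          !mask[ii, jj] && abs(m[ii, jj] - v0) <= tol) {
        mask[ii, jj] <- TRUE
        queue[[length(queue) + 1]] <- c(ii, jj)
      }
    }
  }
  mask
}

# MSD by brute-force double loop over all (t, t + tau) pairs
oracle_msd <- function(track, pixel_size = 1) {
  fr <- track$frame; x <- track$x; y <- track$y
  span <- max(fr) - min(fr)
  res <- data.frame(lag = integer(0), msd = numeric(0))
  for (tau in seq_len(span)) {
    acc <- c()
    for (a in seq_along(fr)) for (b in seq_along(fr)) {
      if (fr[b] - fr[a] == tau)
        acc <- c(acc, (x[b] - x[a])^2 + (y[b] - y[a])^2)
    }
    if (length(acc) > 0)
      res <- rbind(res, data.frame(lag = tau, msd = mean(acc) * pixel_size^2))
  }
  res
}

# Z-projection by explicit per-pixel loop over the frame values
oracle_zproject <- function(frames, method) {
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    v <- vapply(frames, function(f) f[i, j], numeric(1))
    out[i, j] <- switch(method,
                        average = mean(v), sum = sum(v), std = sd(v),
                        median = median(v), min = min(v), max = max(v))
  }
  out
}

make_stack <- function(frames, ...) image_stack(frames, ...)

small_capillary <- function(...) {
  simulate_capillary(n_cells = 6, n_frames = 12, width = 320, height = 240,
                     ...)
}
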