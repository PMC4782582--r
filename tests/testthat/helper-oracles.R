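# Independent brute-force oracles used to check the implementation.
# Deliberately written with different algorithms than the package code:
# per-pixel offset gathering for erosion, BFS flood fill for labeling,
# dense pairwise distances for proximity selection, explicit normal
# equations and restarted Lloyd iterations for the fits.

# Erosion by definition: out[p] = all offsets of the disk land on TRUE
# pixels of `m` (outside the image counts as FALSE).
oracle_erode <- function(m, d) {
  H <- nrow(m); W <- ncol(m)
  off <- disk_element(d)$offsets
  out <- matrix(FALSE, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      rr <- r + off[, 1]; cc <- c + off[, 2]
      if (any(rr < 1 | rr > H | cc < 1 | cc > W)) next
      out[r, c] <- all(m[cbind(rr, cc)])
    }
  }
  out
}

# BFS flood-fill labeling; returns an integer label map with labels in
# raster order (row-major) of each component's first pixel.
oracle_flood_fill <- function(m, connectivity = 8L) {
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  }
  nl <- 0L
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (!m[r, c] || lab[r, c] != 0L) next
    nl <- nl + 1L
    queue <- matrix(c(r, c), 1)
    lab[r, c] <- nl
    while (nrow(queue) > 0L) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_along(dr)) {
        rr <- p[1] + dr[k]; cc <- p[2] + dc[k]
        if (rr >= 1L && rr <= H && cc >= 1L && cc <= W &&
            m[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nl
          queue <- rbind(queue, c(rr, cc))
        }
      }
    }
  }
  lab
}

# Restarted Lloyd's iterations on a numeric vector, returning the best
# (minimum) within-cluster sum of squares over `restarts` random starts.
oracle_lloyd_best_wss <- function(x, K, restarts = 50L, seed = 1L) {
  lloyd <- function(centers) {
    for (it in 1:300) {
      dmat <- abs(outer(x, centers, "-"))
      assign_k <- max.col(-dmat, ties.method = "first")
      new_centers <- vapply(seq_len(K), function(k) {
        xi <- x[assign_k == k]
        if (length(xi)) mean(xi) else centers[k]
      }, numeric(1))
      if (max(abs(new_centers - centers)) < 1e-12) break
      centers <- new_centers
    }
    dmat <- abs(outer(x, centers, "-"))
    assign_k <- max.col(-dmat, ties.method = "first")
    sum((x - centers[assign_k])^2)
  }
  withr::with_seed(seed, {
    best <- Inf
    for (i in seq_len(restarts)) {
      ctr <- sample(unique(x), K)
      best <- min(best, lloyd(ctr))
    }
    best
  })
}

# Dense pairwise proximity selection.
oracle_select <- function(pts, ref, delta) {
  d2 <- outer(pts[, 1], ref[, 1], "-")^2 + outer(pts[, 2], ref[, 2], "-")^2
  pts[sqrt(apply(d2, 1, min)) <= delta, , drop = FALSE]
}

# Least-squares polynomial coefficients by explicit normal equations.
oracle_polyfit <- function(s, f, degree) {
  X <- outer(s, 0:degree, "^")
  solve(t(X) %*% X, t(X) %*% f)
}

# Exact circle-arc sample points (row = s, col = f frame).
circle_arc_points <- function(R, span_deg, n = 400, quantize = FALSE) {
  th <- seq(-span_deg / 2, span_deg / 2, length.out = n) * pi / 180
  s <- R * sin(th); f <- R - R * cos(th)
  if (quantize) { s <- round(s); f <- round(f) }
  cbind(row = s, col = f)
}

# Small random binary mask.
random_mask <- function(H, W, p = 0.45) matrix(stats::runif(H * W) < p, H, W)

# Standard plate phantom spec used across tests.
plate_test_spec <- function(ratio, seed = 3L, length_px = 320L) {
  phantom_spec(480L, 170L, sl = list(shape = "line", col0 = 55, slope = 0),
               plate = list(ratio = ratio, length_px = length_px, width = 6L),
               seed = seed)
}
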