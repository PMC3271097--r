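# Brute-force oracles and small fixtures shared across tests.  Every oracle
# here is deliberately independent of the package's computation path.

# Multi-stage grid search for the point minimising the variance of
# distances to three anchors (the circumcenter), final step 0.001 deg.
grid_circumcenter <- function(p1, p2, p3, span = 10, fine_step = 0.001) {
  pts <- rbind(p1, p2, p3)
  ctr <- colMeans(pts)
  obj <- function(gx, gy) {
    best <- c(NA, NA); best_v <- Inf
    for (x in gx) {
      d1 <- sqrt((x - pts[1, 1])^2 + (gy - pts[1, 2])^2)
      d2 <- sqrt((x - pts[2, 1])^2 + (gy - pts[2, 2])^2)
      d3 <- sqrt((x - pts[3, 1])^2 + (gy - pts[3, 2])^2)
      v <- ((d1 - d2)^2 + (d2 - d3)^2 + (d1 - d3)^2)
      if (min(v) < best_v) {
        best_v <- min(v)
        best <- c(x, gy[which.min(v)])
      }
    }
    best
  }
  cur <- ctr
  half <- span
  for (step in c(0.05, 0.01, fine_step)) {
    cur <- obj(seq(cur[1] - half, cur[1] + half, by = step),
               seq(cur[2] - half, cur[2] + half, by = step))
    half <- step * 12    # next window comfortably covers the grid error
  }
  cur
}

# Grid search for the translation minimising the SSD between two center
# layouts, final step 0.001 deg.
grid_translation <- function(face_centers, reference_centers,
                             span = 5, fine_step = 0.001) {
  fc <- as.matrix(face_centers[, c("x", "y")])
  rc <- as.matrix(reference_centers[, c("x", "y")])
  ssd <- function(dx, dy)
    sum((fc[, 1] + dx - rc[, 1])^2 + (fc[, 2] + dy - rc[, 2])^2)
  search <- function(cx, cy, half, step) {
    gx <- seq(cx - half, cx + half, by = step)
    gy <- seq(cy - half, cy + half, by = step)
    best <- c(NA, NA); best_v <- Inf
    for (dx in gx) for (dy in gy) {
      v <- ssd(dx, dy)
      if (v < best_v) { best_v <- v; best <- c(dx, dy) }
    }
    best
  }
  coarse <- search(0, 0, span, 0.05)
  search(coarse[1], coarse[2], 0.06, fine_step)
}

# 1-D search along the perpendicular bisector of anchors p, q for the point
# at distance d from each, on the side away from `away_from`.
grid_vertical_start <- function(p, q, d, away_from, fine_step = 0.001) {
  m <- (p + q) / 2
  dirv <- (q - p) / sqrt(sum((q - p)^2))
  normal <- c(-dirv[2], dirv[1])
  best_for <- function(ts) {
    cand_x <- m[1] + ts * normal[1]
    cand_y <- m[2] + ts * normal[2]
    err <- abs(sqrt((cand_x - p[1])^2 + (cand_y - p[2])^2) - d)
    c(ts[which.min(err)], min(err))
  }
  pos <- best_for(seq(0.001, 2 * d + 1, by = 0.05))
  neg <- best_for(seq(-2 * d - 1, -0.001, by = 0.05))
  refine <- function(t0) best_for(seq(t0 - 0.06, t0 + 0.06, by = fine_step))
  pos <- refine(pos[1]); neg <- refine(neg[1])
  cands <- rbind(c(m + pos[1] * normal), c(m + neg[1] * normal))
  d2 <- rowSums((cands - matrix(away_from, 2, 2, byrow = TRUE))^2)
  cands[which.max(d2), ]
}

# Dense Gaussian density map evaluated directly, with the method's declared
# per-axis 4-sigma kernel truncation.
dense_density <- function(x, y, grid, sigma = 0.3, trunc = 4) {
  gx <- grid$x_min + (seq_len(grid$n_x) - 0.5) * grid$cell
  gy <- grid$y_min + (seq_len(grid$n_y) - 0.5) * grid$cell
  r <- trunc * sigma + 1e-9
  vals <- matrix(0, grid$n_x, grid$n_y)
  for (i in seq_along(x)) {
    wx <- ifelse(abs(gx - x[i]) <= r, dnorm(gx, x[i], sigma), 0)
    wy <- ifelse(abs(gy - y[i]) <= r, dnorm(gy, y[i], sigma), 0)
    vals <- vals + outer(wx, wy)
  }
  vals
}

# Recursive flood fill connected-component labelling over a signed mask.
floodfill_clusters <- function(mask, connectivity = 8) {
  n_x <- nrow(mask); n_y <- ncol(mask)
  seen <- matrix(FALSE, n_x, n_y)
  offs <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  out <- list()
  for (j in seq_len(n_y)) for (i in seq_len(n_x)) {
    if (mask[i, j] == 0 || seen[i, j]) next
    s <- mask[i, j]
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, (cur[2] - 1) * n_x + cur[1])
      for (o in seq_len(nrow(offs))) {
        ni <- cur[1] + offs[o, 1]; nj <- cur[2] + offs[o, 2]
        if (ni >= 1 && ni <= n_x && nj >= 1 && nj <= n_y &&
            !seen[ni, nj] && mask[ni, nj] == s) {
          seen[ni, nj] <- TRUE
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
    out[[length(out) + 1]] <- list(sign = s, pixels = sort(comp))
  }
  out
}

# Random non-degenerate triangle (anchor triple) in a +/- 5 deg box.  The
# area and circumradius (R = abc / 4K) gates keep the variance-of-distances
# objective well conditioned, so the grid oracle's argmin is identifiable
# at its step size; the closed form's defining equidistance property is
# asserted separately on unconstrained triangles.
random_triangle <- function(max_radius = 6, min_area = 2) {
  repeat {
    p <- matrix(runif(6, -5, 5), 3, 2)
    area <- abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
                  (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) / 2
    if (area < min_area) next
    sides <- c(sqrt(sum((p[1, ] - p[2, ])^2)),
               sqrt(sum((p[2, ] - p[3, ])^2)),
               sqrt(sum((p[1, ] - p[3, ])^2)))
    if (prod(sides) / (4 * area) < max_radius) return(p)
  }
}

# Tiny two-participant fixation table with 3 exchangeable (1,1) strata,
# giving exactly 2^3 = 8 permutation assignments.
toy_exchangeable_data <- function() {
  data.frame(
    participant_id = c("p1", "p1", "p1", "p1", "p2", "p2"),
    trial_id = c("a1", "a1", "b1", "b1", "a2", "b2"),
    condition = c("A", "A", "B", "B", "A", "B"),
    ordinal = c(1L, 2L, 1L, 2L, 1L, 1L),
    x = c(-0.8, 0.5, 0.9, -0.3, 0.2, -1.1),
    y = c(0.4, -0.6, 0.1, 0.8, -0.9, 0.3),
    onset_ms = c(200, 500, 210, 520, 190, 205),
    duration_ms = c(250, 260, 240, 270, 255, 245),
    stringsAsFactors = FALSE)
}

# Exhaustive enumeration of the 8 stratum assignments of the toy data:
# group difference maps via the dense oracle, and exact two-sided-by-sign
# p-values (identity assignment included in the reference set).
toy_exact_pvalues <- function(fx, grid, sigma = 0.3) {
  strata <- list(c(1, 3), c(2, 4), c(5, 6))   # (A-row, B-row) per stratum
  diff_of <- function(fx2) {
    # participant means of (A trial-mean - B trial-mean); 1 trial each side
    d1 <- dense_density(fx2$x[fx2$trial_id == "a1"],
                        fx2$y[fx2$trial_id == "a1"], grid, sigma) -
          dense_density(fx2$x[fx2$trial_id == "b1"],
                        fx2$y[fx2$trial_id == "b1"], grid, sigma)
    d2 <- dense_density(fx2$x[fx2$trial_id == "a2"],
                        fx2$y[fx2$trial_id == "a2"], grid, sigma) -
          dense_density(fx2$x[fx2$trial_id == "b2"],
                        fx2$y[fx2$trial_id == "b2"], grid, sigma)
    (d1 + d2) / 2
  }
  maps <- list()
  for (bits in 0:7) {
    fx2 <- fx
    for (s in 1:3) {
      if (bitwAnd(bits, bitwShiftL(1, s - 1)) > 0) {
        a <- strata[[s]][1]; b <- strata[[s]][2]
        fx2[c(a, b), c("x", "y")] <- fx[c(b, a), c("x", "y")]
      }
    }
    maps[[bits + 1]] <- diff_of(fx2)
  }
  true_map <- maps[[1]]
  p <- matrix(0, grid$n_x, grid$n_y)
  # tolerance keeps mathematically exact ties (assignments that only swap
  # locations far from the pixel) from being broken by float-path noise
  eps <- 1e-9
  for (i in seq_len(grid$n_x)) for (j in seq_len(grid$n_y)) {
    v <- true_map[i, j]
    vals <- vapply(maps, function(m) m[i, j], 0)
    p[i, j] <- if (v >= 0) mean(vals >= v - eps) else mean(vals <= v + eps)
  }
  list(p = p, true_map = true_map)
}
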