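# Independent brute-force oracles used to validate the package's algorithms.
# These deliberately share no code with the implementation.

# 8-connected component labeling by breadth-first flood fill.
oracle_label <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di
        nj <- p[2] + dj
        if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
            mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- nxt
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# Particle list (area, centroid) from the flood-fill labels, as a canonical
# set (sorted by x then y) for comparison with detect_particles().
oracle_particles <- function(mask, min_area = 1) {
  lab <- oracle_label(mask)
  out <- data.frame(x = numeric(0), y = numeric(0), area = integer(0))
  if (max(lab) == 0L) return(out)
  for (k in seq_len(max(lab))) {
    ij <- which(lab == k, arr.ind = TRUE)
    if (nrow(ij) < min_area) next
    out <- rbind(out, data.frame(x = mean(ij[, 2]), y = mean(ij[, 1]),
                                 area = nrow(ij)))
  }
  out[order(out$x, out$y, out$area), , drop = FALSE]
}

canon_particles <- function(df) {
  df <- df[order(df$x, df$y, df$area), c("x", "y", "area"), drop = FALSE]
  rownames(df) <- NULL
  df
}

# Scan-based run-length bout oracle (no rle()).
oracle_bouts <- function(qualifies) {
  res <- data.frame(bout = integer(0), start_window = integer(0),
                    n_windows = integer(0))
  in_bout <- FALSE
  for (i in seq_along(qualifies)) {
    if (qualifies[i] && !in_bout) {
      res <- rbind(res, data.frame(bout = nrow(res) + 1L,
                                   start_window = i - 1L, n_windows = 1L))
      in_bout <- TRUE
    } else if (qualifies[i]) {
      res$n_windows[nrow(res)] <- res$n_windows[nrow(res)] + 1L
    } else {
      in_bout <- FALSE
    }
  }
  res
}

# Exact two-sided rank-sum p by enumerating all 2^n group assignments with
# the observed group sizes (bitmask enumeration, independent of combn()).
oracle_ranksum_p <- function(a, b) {
  v <- c(a, b)
  n <- length(v)
  n1 <- length(a)
  rk <- rank(v)
  w_obs <- sum(rk[seq_len(n1)])
  sums <- c()
  for (m in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(m))[1:n]
    if (sum(bits) != n1) next
    sums <- c(sums, sum(rk[bits == 1L]))
  }
  eps <- 1e-9
  min(1, 2 * min(mean(sums <= w_obs + eps), mean(sums >= w_obs - eps)))
}

# small arena for fast renders
tiny_arena <- function() {
  arena_spec(width_px = 120, height_px = 100, dish_center = c(60, 50),
             dish_radius_px = 45, food_center = c(60, 50),
             food_radius_px = 8, frame_interval_s = 3)
}

# regime active enough that background modelling is valid
active_params <- function(...) {
  mock_params(bout_rate_per_h = 30, bout_duration_mean_s = 300,
              step_mean_px = 3, ...)
}
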