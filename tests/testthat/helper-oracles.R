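# Independent oracles, deliberately written as plain loops so they share no
# code with the implementation they check.

# Piecewise-linear interpolation with nearest-value edge extension.
oracle_interp <- function(x) {
  obs <- which(!is.na(x))
  out <- x
  for (t in seq_along(x)) {
    if (!is.na(x[t])) next
    left <- obs[obs < t]
    right <- obs[obs > t]
    if (!length(left)) {
      out[t] <- x[right[1]]
    } else if (!length(right)) {
      out[t] <- x[left[length(left)]]
    } else {
      l <- left[length(left)]; r <- right[1]
      out[t] <- x[l] + (x[r] - x[l]) * (t - l) / (r - l)
    }
  }
  out
}

# Brute-force truncated-Gaussian convolution with renormalized edges.
oracle_smooth <- function(x, window = 5L, sigma = 1) {
  h <- (window - 1L) %/% 2L
  out <- numeric(length(x))
  for (t in seq_along(x)) {
    acc <- 0; wsum <- 0
    for (k in -h:h) {
      j <- t + k
      if (j >= 1 && j <= length(x)) {
        w <- exp(-(k / sigma)^2 / 2)
        acc <- acc + w * x[j]
        wsum <- wsum + w
      }
    }
    out[t] <- acc / wsum
  }
  out
}

# Exact Wilcoxon rank-sum p-value by full enumeration of group labelings.
oracle_wilcoxon <- function(a, b, alternative) {
  pool <- c(a, b)
  r <- rank(pool)
  na <- length(a)
  w_obs <- sum(r[seq_len(na)])
  picks <- utils::combn(length(pool), na)
  ws <- apply(picks, 2, function(ix) sum(r[ix]))
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  switch(alternative,
         less = p_le,
         greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

# Brute-force nearest-source-center search for every target cell, ties
# broken toward the smaller source row then column.
oracle_remap <- function(values, src, dst) {
  out <- matrix(values[1], dst$n_rows, dst$n_cols)
  for (i in seq_len(dst$n_rows)) {
    for (j in seq_len(dst$n_cols)) {
      tx <- dst$origin_x + (j - 0.5) * dst$pixel_size
      ty <- dst$origin_y - (i - 0.5) * dst$pixel_size
      best <- Inf; br <- 1L; bc <- 1L
      for (r in seq_len(src$n_rows)) {
        for (c in seq_len(src$n_cols)) {
          sx <- src$origin_x + (c - 0.5) * src$pixel_size
          sy <- src$origin_y - (r - 0.5) * src$pixel_size
          d2 <- (tx - sx)^2 + (ty - sy)^2
          if (d2 < best - 1e-9) {
            best <- d2; br <- r; bc <- c
          }
        }
      }
      out[i, j] <- values[br, bc]
    }
  }
  out
}

# Small scene shared by several tests (cheap: 8 x 8, 5 years).
tiny_scene <- function(seed = 11L, ...) {
  generate_scene(scene_config(n_rows = 8L, n_cols = 8L, years = 2001:2005,
                              seed = seed, ...))
}
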