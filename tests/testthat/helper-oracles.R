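# Brute-force oracles: every G statistic re-evaluated with plain nested
# loops from raw count tables, independent of the package's vectorized
# counting. Used to pin the implementations to the likelihood-ratio
# formulas.

xlogy <- function(x, y) if (x > 0) x * log(y) else 0

oracle_counts <- function(x, ns, k) {
  # k-gram counts as a k-dimensional array via explicit loops
  f <- array(0, dim = rep(ns, k))
  for (t in seq_len(length(x) - k + 1L)) {
    idx <- matrix(x[t:(t + k - 1L)] + 1L, nrow = 1)
    f[idx] <- f[idx] + 1
  }
  f
}

oracle_g0 <- function(x, ns) {
  f <- oracle_counts(x, ns, 2L)
  n <- sum(f)
  fi <- rowSums(f)
  fj <- colSums(f)
  G <- 0
  for (i in 1:ns) for (j in 1:ns) {
    if (f[i, j] > 0) G <- G + xlogy(f[i, j], n * f[i, j] / (fi[i] * fj[j]))
  }
  2 * G
}

oracle_g1a <- function(x, ns) {
  f <- oracle_counts(x, ns, 3L)
  G <- 0
  for (i in 1:ns) for (j in 1:ns) for (k in 1:ns) {
    if (f[i, j, k] > 0) {
      fij <- sum(f[i, j, ])
      fjk <- sum(f[, j, k])
      fj <- sum(f[, j, ])
      G <- G + xlogy(f[i, j, k], f[i, j, k] * fj / (fij * fjk))
    }
  }
  2 * G
}

oracle_g2 <- function(x, ns) {
  f <- oracle_counts(x, ns, 4L)
  G <- 0
  for (i in 1:ns) for (j in 1:ns) for (k in 1:ns) for (l in 1:ns) {
    if (f[i, j, k, l] > 0) {
      fijk <- sum(f[i, j, k, ])
      fjkl <- sum(f[, j, k, l])
      fjk <- sum(f[, j, k, ])
      G <- G + xlogy(f[i, j, k, l], f[i, j, k, l] * fjk / (fijk * fjkl))
    }
  }
  2 * G
}

oracle_g3 <- function(x, ns, L) {
  n <- length(x)
  r <- n %/% L
  f <- array(0, dim = c(r, ns, ns))          # [block, from, to]
  for (b in seq_len(r)) {
    for (t in seq_len(L - 1L)) {
      i <- x[(b - 1L) * L + t] + 1L
      j <- x[(b - 1L) * L + t + 1L] + 1L
      f[b, i, j] <- f[b, i, j] + 1
    }
  }
  G <- 0
  for (b in 1:r) for (i in 1:ns) for (j in 1:ns) {
    if (f[b, i, j] > 0) {
      f_i <- sum(f[, i, ])                   # pooled from-counts
      f_bi <- sum(f[b, i, ])                 # from-counts in block b
      f_ij <- sum(f[, i, j])                 # pooled i -> j
      G <- G + xlogy(f[b, i, j], f[b, i, j] * f_i / (f_bi * f_ij))
    }
  }
  2 * G
}

oracle_g4 <- function(x, ns) {
  f <- oracle_counts(x, ns, 2L)
  G <- 0
  for (i in 1:ns) for (j in 1:ns) {
    if (i != j && f[i, j] > 0) {
      G <- G + xlogy(f[i, j], 2 * f[i, j] / (f[i, j] + f[j, i]))
    }
  }
  2 * G
}

oracle_g1b <- function(x, ns, state) {
  r <- rle(x)
  lens <- r$lengths[r$values == state]
  R <- length(lens)
  m <- max(lens)
  p <- tabulate(lens, m) / R
  # geometric parameter from the first-order transition matrix
  f <- oracle_counts(x, ns, 2L)
  tii <- f[state + 1, state + 1] / sum(f[state + 1, ])
  q <- (1 - tii) * tii^(0:(m - 1))
  q <- q / sum(q)
  G <- 0
  for (k in seq_len(m)) if (p[k] > 0) G <- G + xlogy(p[k], p[k] / q[k])
  2 * R * G
}

# exact best-permutation matching of recovered maps to ground truth by
# mean absolute spatial correlation (n_maps small, so enumerate)
match_corr <- function(maps, truth) {
  norm_rows <- function(m) {
    m <- m - rowMeans(m)
    m / sqrt(rowSums(m^2))
  }
  cc <- abs(norm_rows(maps) %*% t(norm_rows(truth)))
  k <- nrow(cc)
  perms <- gtools_permutations(k)
  best <- -Inf
  best_corr <- NULL
  for (p in seq_len(nrow(perms))) {
    v <- cc[cbind(seq_len(k), perms[p, ])]
    if (mean(v) > best) {
      best <- mean(v)
      best_corr <- v
    }
  }
  best_corr
}

gtools_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(k - 1L)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# representative resting-state 4-state transition matrix (diagonal-heavy),
# rows renormalized to sum exactly to 1
eeg_like_T <- function() {
  T <- matrix(c(
    0.799, 0.071, 0.069, 0.061,
    0.079, 0.771, 0.094, 0.057,
    0.053, 0.064, 0.767, 0.116,
    0.099, 0.061, 0.056, 0.784
  ), 4, 4, byrow = TRUE)
  T / rowSums(T)
}

eeg_like_pi <- function() {
  p <- c(0.279, 0.222, 0.235, 0.264)
  p / sum(p)
}

random_stochastic_matrix <- function(ns, conc = 1) {
  T <- matrix(rgamma(ns * ns, shape = conc), ns, ns)
  T / rowSums(T)
}

# small synthetic cap: electrodes on a hemisphere
demo_layout <- function(n_ch = 30L) {
  g <- seq(0, 2 * pi, length.out = n_ch + 1L)[seq_len(n_ch)]
  r <- rep(seq(0.3, 1, length.out = ceiling(n_ch / 6)), length.out = n_ch)
  as_electrode_layout(tibble::tibble(
    label = paste0("E", seq_len(n_ch)),
    x = r * cos(g), y = r * sin(g), z = sqrt(pmax(0, 1 - r^2))
  ))
}
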