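# Likelihood-ratio (G) tests for the symbolic dynamics of microstate
# sequences: Markov order 0/1/2, geometric lifetimes, stationarity and
# symmetry of the transition matrix. All statistics follow the convention
# that zero-count cells contribute zero (x log x -> 0), and p-values are
# the chi-square upper tail at the stated degrees of freedom.

new_gtest <- function(statistic, df, method, data.name, ...) {
  structure(
    c(list(
      statistic = c(G = statistic),
      parameter = c(df = df),
      p.value = pchisq(statistic, df, lower.tail = FALSE),
      method = method,
      data.name = data.name
    ), list(...)),
    class = c("gtest", "htest")
  )
}

#' Zero-order Markov (independence) test
#'
#' Tests whether the next label is independent of the current one,
#' `P(X_{t+1} | X_t) = P(X_{t+1})`, with the likelihood-ratio statistic
#' `G0 = 2 sum_ij f_ij log(n f_ij / (f_i f_j))` over the `n - 1`
#' transition windows; `df = (n_s - 1)^2`.
#'
#' @param seq A [label_sequence()] or integer vector of 0-based labels.
#' @return A `gtest` object (printable like an `htest`), with elements
#'   `statistic`, `parameter` (df), `p.value`.
#' @export
test_markov0 <- function(seq) {
  dn <- deparse(substitute(seq))
  seq <- as_label_sequence(seq)
  ns <- n_states_of(seq)
  f <- pair_counts(unclass(seq), ns)
  N <- sum(f)
  fi <- rowSums(f)
  fj <- colSums(f)
  idx <- which(f > 0, arr.ind = TRUE)
  cells <- f[idx]
  G <- 2 * sum(cells * log(N * cells / (fi[idx[, 1]] * fj[idx[, 2]])))
  new_gtest(G, (ns - 1)^2, "G-test of zero-order Markovianity (independence)",
            dn)
}

#' First-order Markov test
#'
#' Tests `P(X_{t+1} | X_t, X_{t-1}) = P(X_{t+1} | X_t)` via triplet counts
#' `f_ijk` over overlapping windows:
#' `G1a = 2 sum_ijk f_ijk log(f_ijk f_j / (f_ij f_jk))`;
#' `df = n_s (n_s - 1)^2`.
#'
#' @inheritParams test_markov0
#' @return A `gtest` object.
#' @export
test_markov1 <- function(seq) {
  dn <- deparse(substitute(seq))
  seq <- as_label_sequence(seq)
  ns <- n_states_of(seq)
  if (length(seq) < 3L) stop("need at least 3 samples")
  f3 <- ngram_array(unclass(seq), ns, 3L)
  f_ij <- apply(f3, c(1, 2), sum)
  f_jk <- apply(f3, c(2, 3), sum)
  f_j <- apply(f3, 2, sum)
  idx <- which(f3 > 0, arr.ind = TRUE)
  cells <- f3[idx]
  G <- 2 * sum(cells * log(
    cells * f_j[idx[, 2]] /
      (f_ij[idx[, c(1, 2), drop = FALSE]] * f_jk[idx[, c(2, 3), drop = FALSE]])
  ))
  new_gtest(G, ns * (ns - 1)^2, "G-test of first-order Markovianity", dn)
}

#' Second-order Markov test
#'
#' Tests `P(X_{t+1} | X_t, X_{t-1}, X_{t-2}) = P(X_{t+1} | X_t, X_{t-1})`
#' via quadruplet counts:
#' `G2 = 2 sum_ijkl f_ijkl log(f_ijkl f_jk / (f_ijk f_jkl))`;
#' `df = n_s^2 (n_s - 1)^2`.
#'
#' @inheritParams test_markov0
#' @return A `gtest` object.
#' @export
test_markov2 <- function(seq) {
  dn <- deparse(substitute(seq))
  seq <- as_label_sequence(seq)
  ns <- n_states_of(seq)
  if (length(seq) < 4L) stop("need at least 4 samples")
  f4 <- ngram_array(unclass(seq), ns, 4L)
  f_ijk <- apply(f4, c(1, 2, 3), sum)
  f_jkl <- apply(f4, c(2, 3, 4), sum)
  f_jk <- apply(f4, c(2, 3), sum)
  idx <- which(f4 > 0, arr.ind = TRUE)
  cells <- f4[idx]
  G <- 2 * sum(cells * log(
    cells * f_jk[idx[, c(2, 3), drop = FALSE]] /
      (f_ijk[idx[, c(1, 2, 3), drop = FALSE]] *
         f_jkl[idx[, c(2, 3, 4), drop = FALSE]])
  ))
  new_gtest(G, ns^2 * (ns - 1)^2, "G-test of second-order Markovianity", dn)
}

#' Lifetime (dwell time) distribution of one state
#'
#' Histogram of the lengths of contiguous runs of `state`, normalized to a
#' probability vector over lifetimes `1 .. m` (`m` = longest observed
#' run), together with the geometric model
#' `q(k) = (1 - T_ii) T_ii^(k-1)` implied by the first-order transition
#' matrix.
#'
#' @inheritParams test_markov0
#' @param state 0-based label whose lifetimes are collected.
#' @return A `lifetime_distribution`: list with `state`, `m`, `n_runs`,
#'   `p_emp` (length `m`), `q_geom` (length `m`, unnormalized geometric
#'   law), `t_ii`.
#' @export
lifetime_distribution <- function(seq, state) {
  seq <- as_label_sequence(seq)
  r <- rle(as.integer(seq))
  lens <- r$lengths[r$values == state]
  if (length(lens) == 0L) stop("state ", state, " does not occur in `seq`")
  m <- max(lens)
  p_emp <- tabulate(lens, nbins = m) / length(lens)
  tm <- suppressWarnings(transition_matrix(seq))
  t_ii <- tm$T[state + 1L, state + 1L]
  q_geom <- (1 - t_ii) * t_ii^(seq_len(m) - 1)
  structure(
    list(state = state, m = m, n_runs = length(lens), p_emp = p_emp,
         q_geom = q_geom, t_ii = t_ii),
    class = "lifetime_distribution"
  )
}

#' Geometric lifetime tests (first-order Markovianity per state)
#'
#' For a first-order Markov chain, each state's lifetime distribution is
#' geometric with parameter `T_ii`. Per state `i`, the statistic is the
#' run-count-weighted G form
#' `G1b = 2 R_i sum_k p(k) log(p(k) / q(k))`, with the geometric model
#' renormalized over the observed support `1 .. m`; `df = m - 1`. States
#' with fewer than 2 runs, or that never exit (`T_ii = 1`), are skipped.
#'
#' @inheritParams test_markov0
#' @return A `gtest_set`: named list of `gtest` objects, one per tested
#'   state (`"state_0"`, `"state_1"`, ...).
#' @export
test_geometric_lifetimes <- function(seq) {
  dn <- deparse(substitute(seq))
  seq <- as_label_sequence(seq)
  ns <- n_states_of(seq)
  present <- sort(unique(as.integer(seq)))
  out <- list()
  for (s in present) {
    ld <- lifetime_distribution(seq, s)
    if (ld$n_runs < 2L || ld$t_ii >= 1) next
    q <- ld$q_geom / sum(ld$q_geom)
    p <- ld$p_emp
    nz <- p > 0
    G <- 2 * ld$n_runs * sum(p[nz] * log(p[nz] / q[nz]))
    df <- max(ld$m - 1L, 1L)
    out[[paste0("state_", s)]] <- new_gtest(
      G, df, sprintf("G-test of geometric lifetimes (state %d)", s), dn,
      state = s, n_runs = ld$n_runs, m = ld$m
    )
  }
  structure(out, class = "gtest_set")
}

#' @export
print.gtest_set <- function(x, ...) {
  for (g in x) print(g)
  invisible(x)
}

#' Stationarity (conditional homogeneity) test of the transition matrix
#'
#' Partitions the sequence into `floor(n / block_len)` non-overlapping
#' blocks (trailing remainder discarded) and tests whether the within-block
#' transition counts are homogeneous across blocks (Kullback's conditional
#' homogeneity form); only transitions inside a block are counted.
#' `df = (r - 1)(n_s - 1) n_s`.
#'
#' @inheritParams test_markov0
#' @param block_len Block length `L >= 2` in samples; default 5000.
#' @return A `gtest` object with an extra element `blocks` (= `r`).
#' @export
test_stationarity <- function(seq, block_len = 5000L) {
  dn <- deparse(substitute(seq))
  seq <- as_label_sequence(seq)
  ns <- n_states_of(seq)
  n <- length(seq)
  L <- as.integer(block_len)
  if (L < 2L) stop("`block_len` must be at least 2")
  r <- n %/% L
  if (r < 2L) stop("need at least 2 complete blocks; got ", r)
  x <- as.integer(seq)[seq_len(r * L)]
  t_idx <- seq_len(r * L - 1L)
  t_idx <- t_idx[t_idx %% L != 0L]            # drop block-crossing windows
  b <- (t_idx - 1L) %/% L
  code <- b * ns^2 + x[t_idx] * ns + x[t_idx + 1L]
  # array index order is fastest-varying first: [to, from, block]
  f <- array(tabulate(code + 1L, nbins = r * ns^2), dim = c(ns, ns, r))
  f_pair <- apply(f, c(1, 2), sum)             # pooled j -> k: [to, from]
  f_blk <- apply(f, c(2, 3), sum)              # from-state j in block b
  f_from <- apply(f, 2, sum)                   # pooled from-state j
  idx <- which(f > 0, arr.ind = TRUE)          # cols: to, from, block
  cells <- f[idx]
  G <- 2 * sum(cells * log(
    cells * f_from[idx[, 2]] /
      (f_blk[idx[, c(2, 3), drop = FALSE]] * f_pair[idx[, c(1, 2), drop = FALSE]])
  ))
  new_gtest(G, (r - 1L) * (ns - 1L) * ns,
            sprintf("G-test of transition-matrix stationarity (%d blocks of %d)",
                    r, L),
            dn, blocks = r, block_len = L)
}

#' Symmetry test of the transition matrix
#'
#' Tests whether each transition occurs as often as its reverse,
#' `G4 = 2 sum_{i != j} f_ij log(2 f_ij / (f_ij + f_ji))`;
#' `df = n_s (n_s - 1) / 2`.
#'
#' @inheritParams test_markov0
#' @return A `gtest` object.
#' @export
test_symmetry <- function(seq) {
  dn <- deparse(substitute(seq))
  seq <- as_label_sequence(seq)
  ns <- n_states_of(seq)
  f <- pair_counts(unclass(seq), ns)
  idx <- which(f > 0 & row(f) != col(f), arr.ind = TRUE)
  cells <- f[idx]
  rev_cells <- f[idx[, c(2, 1), drop = FALSE]]
  G <- 2 * sum(cells * log(2 * cells / (cells + rev_cells)))
  new_gtest(G, ns * (ns - 1L) / 2L,
            "G-test of transition-matrix symmetry", dn)
}

#' Run the full test battery on a label sequence
#'
#' Computes the zero-, first- and second-order Markov tests, the per-state
#' geometric lifetime tests, the stationarity test and the symmetry test,
#' and returns them as one tidy table with Benjamini-Hochberg adjusted
#' p-values across the battery.
#'
#' @inheritParams test_stationarity
#' @return A tibble with columns `test`, `state`, `statistic`, `df`,
#'   `p_value`, `p_adj`.
#' @examples
#' x <- synthesize_markov_chain(rep(0.25, 4), matrix(0.25, 4, 4), 2000,
#'                              seed = 1)
#' markov_tests(x, block_len = 500)
#' @export
markov_tests <- function(seq, block_len = 5000L) {
  seq <- as_label_sequence(seq)
  one <- function(name, g, state = NA_integer_) {
    tibble::tibble(test = name, state = state,
                   statistic = unname(g$statistic),
                   df = unname(g$parameter), p_value = g$p.value)
  }
  rows <- list(
    one("markov0", test_markov0(seq)),
    one("markov1", test_markov1(seq)),
    one("markov2", test_markov2(seq))
  )
  geo <- test_geometric_lifetimes(seq)
  for (g in geo) rows <- c(rows, list(one("geometric", g, state = g$state)))
  rows <- c(rows, list(
    one("stationarity", test_stationarity(seq, block_len)),
    one("symmetry", test_symmetry(seq))
  ))
  out <- dplyr::bind_rows(rows)
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  out
}
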