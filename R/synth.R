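# Synthetic-data generators: ground-truth topographies, label processes,
# and full synthetic EEG. These make every pipeline stage testable without
# any recorded EEG.

#' Synthesize smooth ground-truth topographies
#'
#' Draws `n_maps` spatially smooth random fields over an electrode layout
#' (Gaussian-kernel covariance on the electrode coordinates), then
#' orthogonalizes them against each other and against the constant vector,
#' yielding zero-mean, unit-norm, mutually near-uncorrelated topographies
#' (pairwise `|correlation| <= 0.5` by construction).
#'
#' @param layout An `electrode_layout` with at least `n_maps` electrodes.
#' @param n_maps Number of maps (`>= 2`).
#' @param seed Optional integer seed.
#' @param smoothness Kernel length scale relative to the layout diameter;
#'   default 0.5.
#' @return Numeric matrix `(n_maps, n_ch)` with channel-name columns.
#' @export
synth_maps <- function(layout, n_maps, seed = NULL, smoothness = 0.5) {
  layout <- as_electrode_layout(layout)
  n_ch <- nrow(layout)
  n_maps <- as.integer(n_maps)
  if (n_maps < 2L) stop("`n_maps` must be at least 2")
  if (n_maps > n_ch) stop("cannot draw more maps than electrodes")
  if (!is.null(seed)) set.seed(seed)
  xyz <- as.matrix(layout[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  ell <- smoothness * max(d)
  K <- exp(-(d / ell)^2) + diag(1e-6, n_ch)
  Lc <- chol(K)
  raw <- matrix(rnorm(n_maps * n_ch), n_maps, n_ch) %*% Lc
  # orthogonalize against the constant vector and each other (QR of the
  # stacked basis), then renormalize: zero-mean rows, pairwise corr ~ 0
  basis <- rbind(rep(1, n_ch), raw)
  Q <- qr.Q(qr(t(basis)))[, -1L, drop = FALSE]       # drop constant direction
  maps <- t(Q)[seq_len(n_maps), , drop = FALSE]
  maps <- maps - rowMeans(maps)
  maps <- maps / sqrt(rowSums(maps^2))
  colnames(maps) <- layout$label
  maps
}

#' Synthesize a label process
#'
#' Generates symbolic sequences under one of four generating laws:
#' \describe{
#'   \item{`markov`}{first-order Markov chain from `pi` and `T`
#'     (delegates to [synthesize_markov_chain()]).}
#'   \item{`semi_markov`}{state runs drawn from an explicit lifetime law
#'     (`lifetimes`: a function `(state, n_runs) -> integer lengths`, or a
#'     single fixed run length), with successor states drawn from the
#'     off-diagonal part of `T` (no self-transitions); non-geometric
#'     lifetimes violate first-order Markovianity.}
#'   \item{`higher_order`}{samples from an explicit conditional table
#'     `cond`: a matrix `(n_states^order, n_states)` of probabilities
#'     `P(next | context)`, contexts encoded little-endian (oldest symbol
#'     is the lowest digit).}
#'   \item{`periodic`}{deterministically repeats `cycle`, holding each
#'     symbol for `dwell` samples.}
#' }
#'
#' @param mode One of `"markov"`, `"semi_markov"`, `"higher_order"`,
#'   `"periodic"`.
#' @param n Output length.
#' @param pi,T Markov parameters (modes `markov`, `semi_markov`).
#' @param lifetimes Lifetime law for `semi_markov`: a positive integer
#'   (fixed run length) or a function `(state, n_runs)`.
#' @param cond Conditional probability table for `higher_order`.
#' @param order Memory length of the `higher_order` table.
#' @param cycle,dwell Cycle (0-based labels) and per-symbol dwell for
#'   `periodic`.
#' @param n_states Alphabet size (required for `higher_order`; inferred
#'   otherwise).
#' @param seed Optional integer seed.
#' @return A [label_sequence()] of length `n`.
#' @export
synth_labels <- function(mode = c("markov", "semi_markov", "higher_order",
                                  "periodic"),
                         n, pi = NULL, T = NULL, lifetimes = NULL,
                         cond = NULL, order = 2L, cycle = NULL, dwell = 1L,
                         n_states = NULL, seed = NULL) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  switch(mode,
    markov = {
      if (is.null(pi) || is.null(T)) stop("markov mode needs `pi` and `T`")
      synthesize_markov_chain(pi, T, n)
    },
    semi_markov = {
      if (is.null(T)) stop("semi_markov mode needs `T`")
      T <- as.matrix(T)
      ns <- nrow(T)
      if (is.null(pi)) pi <- rep(1 / ns, ns)
      if (is.null(lifetimes)) stop("semi_markov mode needs `lifetimes`")
      draw_life <- if (is.function(lifetimes)) lifetimes else
        function(state, k) rep(as.integer(lifetimes), k)
      # embedded jump chain: off-diagonal of T, renormalized
      J <- T
      diag(J) <- 0
      rs <- rowSums(J)
      if (any(rs == 0)) stop("semi_markov needs at least one off-diagonal transition per state")
      J <- J / rs
      states <- integer(0)
      lens <- integer(0)
      total <- 0L
      s <- sample.int(ns, 1L, prob = pi) - 1L
      while (total < n) {
        chunk <- max(16L, ceiling((n - total) / 2L))
        st <- integer(chunk)
        ln <- integer(chunk)
        for (i in seq_len(chunk)) {
          st[i] <- s
          ln[i] <- max(1L, as.integer(draw_life(s, 1L)))
          s <- sample.int(ns, 1L, prob = J[s + 1L, ]) - 1L
        }
        states <- c(states, st)
        lens <- c(lens, ln)
        total <- total + sum(ln)
      }
      label_sequence(rep(states, lens)[seq_len(n)], n_states = ns)
    },
    higher_order = {
      if (is.null(cond)) stop("higher_order mode needs `cond`")
      cond <- as.matrix(cond)
      if (is.null(n_states)) n_states <- ncol(cond)
      ns <- as.integer(n_states)
      order <- as.integer(order)
      if (nrow(cond) != ns^order) {
        stop("`cond` must have n_states^order rows")
      }
      if (any(abs(rowSums(cond) - 1) > 1e-9)) {
        stop("rows of `cond` must sum to 1")
      }
      x <- integer(n)
      x[seq_len(order)] <- sample.int(ns, order, replace = TRUE) - 1L
      if (n > order) {
        pw <- ns^(seq_len(order) - 1L)          # little-endian digit weights
        for (t in (order + 1L):n) {
          ctx <- sum(x[(t - order):(t - 1L)] * pw)
          x[t] <- sample.int(ns, 1L, prob = cond[ctx + 1L, ]) - 1L
        }
      }
      label_sequence(x, n_states = ns)
    },
    periodic = {
      if (is.null(cycle)) stop("periodic mode needs `cycle`")
      cycle <- as.integer(cycle)
      dwell <- as.integer(dwell)
      if (dwell < 1L) stop("`dwell` must be at least 1")
      base <- rep(cycle, each = dwell)
      x <- rep_len(base, n)
      label_sequence(x, n_states = max(cycle) + 1L)
    }
  )
}

#' Synthesize a multichannel EEG record from ground truth
#'
#' Builds `x_t = a_t * map[labels_t, ] + noise_t`: each sample is the
#' topography of its hidden label, scaled by a positive amplitude `a_t`
#' (a rectified oscillation at the center of `carrier_band`, modulated by
#' a slow random envelope, emulating amplitude-modulated alpha activity),
#' plus spatially and temporally white Gaussian noise scaled so that the
#' mean per-channel signal variance over the noise variance equals `snr`.
#' `snr = Inf` yields noiseless data.
#'
#' @param maps Ground-truth topographies `(n_maps, n_ch)` (zero-mean,
#'   unit-norm rows, e.g. from [synth_maps()]).
#' @param labels A [label_sequence()]; its length sets `n_t`.
#' @param fs Sampling rate in Hz; default 250.
#' @param carrier_band Oscillation band in Hz; default `c(8, 12)` (alpha).
#' @param snr Signal-to-noise variance ratio (`> 0`); default 5.
#' @param amplitude_uv Root-mean-square amplitude scale in microvolts;
#'   default 15.
#' @param seed Optional integer seed.
#' @return An [eeg_record()] with attribute-free data; the generating
#'   labels are the caller's ground truth.
#' @export
synth_eeg <- function(maps, labels, fs = 250, carrier_band = c(8, 12),
                      snr = 5, amplitude_uv = 15, seed = NULL) {
  maps <- as.matrix(maps)
  labels <- as_label_sequence(labels, n_states = nrow(maps))
  if (max(labels) >= nrow(maps)) stop("labels exceed the number of maps")
  if (!is.numeric(snr) || snr <= 0) stop("`snr` must be positive")
  if (!is.null(seed)) set.seed(seed)
  n_t <- length(labels)
  n_ch <- ncol(maps)
  tt <- (seq_len(n_t) - 1L) / fs

  f_c <- mean(carrier_band)
  carrier <- abs(sin(2 * pi * f_c * tt + runif(1) * 2 * pi))
  # slow random envelope, band-limited 0.2-0.8 Hz, bounded away from zero
  z <- rnorm(n_t)
  if (n_t > 3 / 0.2 * fs) {
    bf <- signal::butter(2, c(0.2, 0.8) / (fs / 2), type = "pass")
    z <- signal::filtfilt(bf, z)
  }
  z <- (z - mean(z)) / max(sd(z), 1e-12)
  env <- pmax(0.25, 1 + 0.5 * z)
  a <- carrier * env
  a <- a / sqrt(mean(a^2)) * amplitude_uv

  x <- a * maps[unclass(labels) + 1L, , drop = FALSE]
  if (is.finite(snr)) {
    sig_var <- mean(x^2)                      # mean per-channel signal power
    noise_sd <- sqrt(sig_var / snr)
    x <- x + matrix(rnorm(n_t * n_ch, sd = noise_sd), n_t, n_ch)
  }
  eeg_record(x, fs = fs, channel_names = colnames(maps))
}
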