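# broom-style tidiers for the package's result objects.

#' Tidy a microstate segmentation
#'
#' @param x A `microstate_segmentation`.
#' @param ... Unused.
#' @return A tibble with one row per map: `map` (0-based), `gev`,
#'   `coverage` (fraction of samples labeled with the map), and
#'   `mean_duration_ms` when the sampling rate is known.
#' @export
tidy.microstate_segmentation <- function(x, ...) {
  cov <- tabulate(x$labels + 1L, nbins = x$n_maps) / length(x$labels)
  r <- rle(x$labels)
  dur <- vapply(0:(x$n_maps - 1L), function(s) {
    l <- r$lengths[r$values == s]
    if (length(l) == 0L) NA_real_ else mean(l)
  }, numeric(1))
  tibble::tibble(
    map = 0:(x$n_maps - 1L),
    gev = x$gev,
    coverage = cov,
    mean_duration_ms = dur / x$fs * 1000
  )
}

#' Summarize a microstate segmentation
#'
#' @param x A `microstate_segmentation`.
#' @param ... Unused.
#' @return One-row tibble: `n_maps`, `n_t`, `n_ch`, `n_gfp_peaks`,
#'   `gev_total`, `cv`, `entropy`, `entropy_max`.
#' @export
glance.microstate_segmentation <- function(x, ...) {
  p <- tabulate(x$labels + 1L, nbins = x$n_maps) / length(x$labels)
  tibble::tibble(
    n_maps = x$n_maps,
    n_t = length(x$labels),
    n_ch = ncol(x$maps),
    n_gfp_peaks = length(x$gfp_peaks),
    gev_total = sum(x$gev),
    cv = x$cv,
    entropy = shannon_entropy(p),
    entropy_max = max_entropy(x$n_maps)
  )
}

#' Tidy a transition model
#'
#' @param x A `transition_model`.
#' @param ... Unused.
#' @return Long tibble with columns `from`, `to` (0-based), `count`,
#'   `prob`.
#' @export
tidy.transition_model <- function(x, ...) {
  ns <- length(x$pi)
  tibble::tibble(
    from = rep(0:(ns - 1L), each = ns),
    to = rep(0:(ns - 1L), times = ns),
    count = as.integer(t(x$counts))[seq_len(ns^2)],
    prob = as.numeric(t(x$T))[seq_len(ns^2)]
  )
}

#' Summarize a transition model
#'
#' @param x A `transition_model`.
#' @param ... Unused.
#' @return One-row tibble: `n_states`, `n`, `entropy`, `entropy_max`.
#' @export
glance.transition_model <- function(x, ...) {
  tibble::tibble(
    n_states = length(x$pi),
    n = x$n,
    entropy = shannon_entropy(x$pi),
    entropy_max = max_entropy(length(x$pi))
  )
}

#' Tidy a G-test result
#'
#' @param x A `gtest`.
#' @param ... Unused.
#' @return One-row tibble: `method`, `statistic`, `df`, `p_value`.
#' @export
tidy.gtest <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = unname(x$statistic),
    df = unname(x$parameter),
    p_value = x$p.value
  )
}

#' Tidy a set of G-tests
#'
#' @param x A `gtest_set` (e.g. from [test_geometric_lifetimes()]).
#' @param ... Unused.
#' @return Tibble with one row per test, plus `state` when present.
#' @export
tidy.gtest_set <- function(x, ...) {
  out <- dplyr::bind_rows(lapply(x, tidy))
  states <- vapply(x, function(g) {
    if (is.null(g$state)) NA_integer_ else as.integer(g$state)
  }, integer(1))
  out$state <- unname(states)
  out
}

#' Tidy an autoinformation result
#'
#' @param x A `microstate_aif`.
#' @param ... Unused.
#' @return The lag table: `lag`, `I_emp`, `I_markov`, `band_lo`,
#'   `band_hi` (and `lag_ms` when the sampling rate is known).
#' @export
tidy.microstate_aif <- function(x, ...) x$table

#' Summarize an autoinformation result
#'
#' @param x A `microstate_aif`.
#' @param ... Unused.
#' @return One-row tibble: `k_max`, `alpha`, `n_surrogates`,
#'   `entropy` (= `I(0)`), `n_lags_above_band`.
#' @export
glance.microstate_aif <- function(x, ...) {
  tbl <- x$table
  tibble::tibble(
    k_max = max(tbl$lag),
    alpha = x$alpha,
    n_surrogates = x$n_surrogates,
    entropy = tbl$I_emp[tbl$lag == 0],
    n_lags_above_band = sum(tbl$I_emp > tbl$band_hi & tbl$lag > 0)
  )
}
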