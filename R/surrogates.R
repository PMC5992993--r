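#' Synthesize a first-order Markov surrogate sequence
#'
#' Generates a label sequence from a symbol distribution `pi` and a
#' row-stochastic transition matrix `T` by inverse-CDF sampling: `pi`
#' partitions the unit interval and a uniform draw selects the initial
#' state; each subsequent state is drawn the same way from the current
#' state's row of `T`, with one fresh uniform draw per step. A surrogate
#' built from the empirical `(pi, T)` of a microstate sequence shares its
#' symbol distribution and transition matrix (up to sampling error) while
#' being first-order Markov by construction.
#'
#' @param pi Probability vector over the `n_s` states.
#' @param T Row-stochastic `n_s x n_s` matrix (rows must sum to 1 within
#'   `1e-9`); alternatively a `transition_model`, in which case `pi` may be
#'   omitted.
#' @param n Output length.
#' @param seed Optional integer seed; the same seed reproduces the
#'   sequence exactly.
#' @return A [label_sequence()] of length `n`.
#' @examples
#' tm <- transition_matrix(c(0L, 0L, 1L, 1L, 0L, 2L, 2L, 1L, 0L))
#' synthesize_markov_chain(tm$pi, tm$T, n = 20, seed = 7)
#' @export
synthesize_markov_chain <- function(pi, T, n, seed = NULL) {
  if (inherits(pi, "transition_model")) {
    T <- pi$T
    pi <- pi$pi
  }
  pi <- as.numeric(pi)
  T <- as.matrix(T)
  ns <- length(pi)
  if (ns < 1L || nrow(T) != ns || ncol(T) != ns) {
    stop("`pi` and `T` have inconsistent dimensions")
  }
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-9) {
    stop("`pi` must be a probability vector")
  }
  if (any(T < 0) || any(abs(rowSums(T) - 1) > 1e-9)) {
    stop("rows of `T` must sum to 1 (within 1e-9)")
  }
  if (n < 1L) stop("`n` must be positive")
  if (!is.null(seed)) set.seed(seed)
  label_sequence(markov_chain_cpp(pi, T, as.integer(n)), n_states = ns)
}
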