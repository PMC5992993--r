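#' Construct a microstate label sequence
#'
#' A symbolic time series of microstate labels, coded as 0-based integers
#' `0 .. n_states - 1` (the field's numeric coding of the maps A, B, C,
#' ...). Externally produced sequences must be recoded to this range.
#'
#' @param labels Integer vector of labels in `0 .. n_states - 1`.
#' @param n_states Alphabet size; defaults to `max(labels) + 1`.
#' @param fs Optional sampling rate in Hz, for time conversion.
#' @return A `label_sequence`: an integer vector with attributes
#'   `n_states` and `fs`.
#' @examples
#' label_sequence(c(0L, 1L, 1L, 2L), n_states = 4)
#' @export
label_sequence <- function(labels, n_states = NULL, fs = NULL) {
  labels <- as.integer(labels)
  if (length(labels) < 1L) stop("a label sequence cannot be empty")
  if (anyNA(labels) || any(labels < 0L)) {
    stop("labels must be non-negative integers (0-based coding)")
  }
  if (is.null(n_states)) n_states <- max(labels) + 1L
  n_states <- as.integer(n_states)
  if (n_states < 1L || any(labels >= n_states)) {
    stop("labels must lie in 0 .. n_states - 1")
  }
  structure(labels, n_states = n_states, fs = fs, class = "label_sequence")
}

as_label_sequence <- function(x, n_states = NULL) {
  if (inherits(x, "label_sequence")) {
    if (!is.null(n_states) && n_states > attr(x, "n_states")) {
      attr(x, "n_states") <- as.integer(n_states)
    }
    return(x)
  }
  label_sequence(x, n_states = n_states)
}

n_states_of <- function(x) attr(x, "n_states")

#' @export
print.label_sequence <- function(x, ...) {
  ns <- n_states_of(x)
  cat(sprintf("<label_sequence> n = %d, alphabet size = %d", length(x), ns))
  fs <- attr(x, "fs")
  if (!is.null(fs)) cat(sprintf(", fs = %g Hz", fs))
  cat("\n  head:", paste(head(unclass(x), 20L), collapse = " "),
      if (length(x) > 20L) "..." else "", "\n")
  invisible(x)
}

#' Empirical symbol distribution
#'
#' Relative frequencies `f_i / n` of each label over the whole sequence
#' (identical to the "ratio of time covered" of each microstate).
#'
#' @param seq A [label_sequence()] or integer vector of 0-based labels.
#' @return Probability vector of length `n_states`.
#' @export
symbol_distribution <- function(seq) {
  seq <- as_label_sequence(seq)
  tabulate(unclass(seq) + 1L, nbins = n_states_of(seq)) / length(seq)
}

#' Shannon entropy of a distribution
#'
#' `H = -sum(p * log(p))` in natural logarithms (nats); zero entries
#' contribute zero.
#'
#' @param p Probability vector (non-negative, summing to 1).
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(p) {
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-8) stop("probabilities must sum to 1")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Maximum entropy of an alphabet
#'
#' The entropy of the uniform distribution over `n_states` symbols,
#' `log(n_states)` nats.
#'
#' @param n_states Alphabet size (`>= 1`).
#' @return Maximum entropy in nats.
#' @export
max_entropy <- function(n_states) {
  if (n_states < 1) stop("`n_states` must be at least 1")
  log(n_states)
}

#' Empirical transition model
#'
#' First-order transition counts `f_ij = #\{t : X_t = i, X_{t+1} = j\}` and
#' the row-normalized transition matrix, together with the symbol
#' distribution over the full sequence. Rows of states never observed as a
#' transition source are set uniform and flagged.
#'
#' @param seq A [label_sequence()] or integer vector of 0-based labels.
#' @return A `transition_model`: list with `pi`, `T`, `counts`, `n`,
#'   `uniform_rows` (0-based indices of unvisited source states).
#' @examples
#' transition_matrix(c(0L, 1L, 0L, 1L, 0L))
#' @export
transition_matrix <- function(seq) {
  seq <- as_label_sequence(seq)
  ns <- n_states_of(seq)
  counts <- pair_counts(unclass(seq), ns)
  rs <- rowSums(counts)
  T <- counts / ifelse(rs > 0, rs, 1)
  uniform_rows <- which(rs == 0) - 1L
  if (length(uniform_rows) > 0L) {
    T[uniform_rows + 1L, ] <- 1 / ns
    warning("states never visited as transition source; rows set uniform: ",
            paste(uniform_rows, collapse = ", "))
  }
  structure(
    list(pi = symbol_distribution(seq), T = T, counts = counts,
         n = length(seq), uniform_rows = uniform_rows),
    class = "transition_model"
  )
}

#' @export
print.transition_model <- function(x, digits = 3, ...) {
  ns <- length(x$pi)
  cat(sprintf("<transition_model> %d states, n = %d\n", ns, x$n))
  cat("  pi:", paste(round(x$pi, digits), collapse = " "), "\n")
  cat("  T:\n")
  print(round(x$T, digits))
  invisible(x)
}

# --- internal n-gram counting -----------------------------------------

# f_ij as an (ns, ns) matrix over the n - 1 transition windows
pair_counts <- function(x, ns) {
  n <- length(x)
  code <- x[-n] * ns + x[-1L]
  matrix(tabulate(code + 1L, nbins = ns^2), ns, ns, byrow = TRUE)
}

# counts of overlapping k-grams as an array indexed [i1, ..., ik]; the
# little-endian code makes symbol d the d-th (fastest-varying first) index
ngram_array <- function(x, ns, k) {
  n <- length(x)
  if (n < k) stop("sequence shorter than n-gram order")
  m <- n - k + 1L
  code <- integer(m)
  for (d in seq_len(k)) {
    # little-endian: symbol d is digit d (fastest-varying)
    code <- code + x[d:(d + m - 1L)] * ns^(d - 1L)
  }
  array(tabulate(code + 1L, nbins = ns^k), dim = rep(ns, k))
}
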