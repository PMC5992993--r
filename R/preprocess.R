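#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass, forward and backward
#' (`signal::filtfilt`), identically to every channel. The zero-phase design
#' introduces no group delay, so topography timing is preserved.
#'
#' @param record An [eeg_record()].
#' @param f_lo,f_hi Band edges in Hz; `0 < f_lo < f_hi < fs/2`.
#' @return A filtered [eeg_record()] of the same shape.
#' @examples
#' rec <- eeg_record(matrix(rnorm(1000 * 3), 1000, 3), fs = 250)
#' filt <- bandpass_filter(rec, 1, 35)
#' @export
bandpass_filter <- function(record, f_lo, f_hi) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$fs
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo <= 0 || f_lo >= f_hi) {
    stop("band edges must satisfy 0 < f_lo < f_hi")
  }
  if (f_hi >= fs / 2) stop("upper band edge must be below the Nyquist frequency")
  bf <- signal::butter(4, c(f_lo, f_hi) / (fs / 2), type = "pass")
  out <- apply(record$data, 2L, function(ch) signal::filtfilt(bf, ch))
  eeg_record(out, fs = fs, channel_names = record$channel_names,
             layout = record$layout)
}

#' Common average reference
#'
#' Subtracts, at each time sample, the mean potential across channels, so
#' every row has zero mean. Idempotent.
#'
#' @param data Numeric matrix `(n_t, n_ch)` or an [eeg_record()].
#' @return Object of the same type, re-referenced.
#' @export
average_reference <- function(data) {
  if (inherits(data, "eeg_record")) {
    data$data <- average_reference(data$data)
    return(data)
  }
  data <- as.matrix(data)
  if (ncol(data) < 2L) stop("average reference needs at least 2 channels")
  data - rowMeans(data)
}

#' Global field power
#'
#' Per time sample, the population standard deviation (divisor `n_ch`) of
#' the potential across channels, computed after average referencing.
#'
#' @param data Numeric matrix `(n_t, n_ch)` or an [eeg_record()].
#' @return Numeric vector of length `n_t`, in microvolts.
#' @export
gfp <- function(data) {
  if (inherits(data, "eeg_record")) data <- data$data
  data <- average_reference(data)
  sqrt(rowMeans(data^2))
}

#' Locate local GFP maxima
#'
#' Returns the indices of strict local maxima of a series. Endpoints are
#' never peaks (the two-sided comparison is undefined there); on plateaus
#' the first plateau index is reported.
#'
#' @param g Numeric vector, length at least 3 (typically a GFP series).
#' @return Integer vector of peak indices (1-based), strictly increasing.
#' @examples
#' find_gfp_peaks(c(1, 2, 1, 3, 1))  # 2, 4
#' @export
find_gfp_peaks <- function(g) {
  if (length(g) < 3L) stop("need at least 3 samples to locate peaks")
  r <- rle(as.numeric(g))
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-k]))
  mid <- 2:(k - 1L)
  is_peak <- r$values[mid] > r$values[mid - 1L] &
    r$values[mid] > r$values[mid + 1L]
  as.integer(starts[mid][is_peak])
}

#' GFP peak rate
#'
#' Number of GFP peaks per second: `length(peaks) * fs / n_t`.
#'
#' @param peaks Integer vector of peak indices.
#' @param n_t Number of time samples in the series.
#' @param fs Sampling rate in Hz.
#' @return Peak rate in peaks per second.
#' @export
peaks_per_second <- function(peaks, n_t, fs) {
  if (n_t <= 0) stop("`n_t` must be positive")
  length(peaks) * fs / n_t
}
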