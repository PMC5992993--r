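#' Construct an EEG record
#'
#' Container for a multichannel EEG segment: a numeric matrix with time
#' samples along the rows and channels along the columns, together with the
#' sampling rate, channel names, and an optional electrode layout.
#'
#' @param data Numeric matrix, shape `(n_t, n_ch)`, in microvolts. Time runs
#'   along the first index.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_names Character vector of length `n_ch`. Defaults to
#'   `"ch1" ... "chN"`.
#' @param layout Optional electrode layout (see [read_xyz()]); its labels
#'   must contain all channel names.
#'
#' @return An object of class `eeg_record`: a list with elements `data`,
#'   `fs`, `channel_names`, `layout`.
#' @examples
#' rec <- eeg_record(matrix(rnorm(500 * 4), 500, 4), fs = 250)
#' rec
#' @export
eeg_record <- function(data, fs, channel_names = NULL, layout = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (nrow(data) < 1L) stop("`data` must have at least one time sample")
  if (ncol(data) < 2L) stop("`data` must have at least two channels")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a positive scalar (Hz)")
  }
  n_ch <- ncol(data)
  if (is.null(channel_names)) {
    channel_names <- if (!is.null(colnames(data))) colnames(data) else
      paste0("ch", seq_len(n_ch))
  }
  channel_names <- as.character(channel_names)
  if (length(channel_names) != n_ch) {
    stop("`channel_names` must have one entry per channel")
  }
  if (!is.null(layout)) {
    layout <- as_electrode_layout(layout)
    if (!all(channel_names %in% layout$label)) {
      stop("`layout` labels must be a superset of the channel names")
    }
  }
  colnames(data) <- channel_names
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         layout = layout),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf(
    "<eeg_record> %d samples x %d channels, fs = %g Hz (%.2f s)\n",
    nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs
  ))
  cat("  channels:", paste(head(x$channel_names, 8L), collapse = ", "),
      if (length(x$channel_names) > 8L) "..." else "", "\n")
  if (!is.null(x$layout)) cat("  layout:", nrow(x$layout), "electrodes\n")
  invisible(x)
}

#' @export
dim.eeg_record <- function(x) dim(x$data)
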