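# Basic EDF (European Data Format, 16-bit) reader/writer.
# Header layout: 256 bytes of ASCII fields, then 256 bytes per signal,
# then data records of interleaved little-endian int16 blocks.

EDF_ANNOTATION_LABEL <- "EDF Annotations"

read_ascii <- function(con, n) {
  raw <- readBin(con, "raw", n = n)
  if (length(raw) < n) stop("malformed EDF header: file truncated")
  trimws(rawToChar(raw))
}

num_field <- function(s, what) {
  x <- suppressWarnings(as.numeric(s))
  if (is.na(x)) stop(sprintf("malformed EDF header: non-numeric %s ('%s')", what, s))
  x
}

#' Read an EDF file
#'
#' Reads a plain EDF or EDF+C file (16-bit samples) into an [eeg_record()].
#' Samples are scaled to physical units using each signal's physical/digital
#' minimum and maximum. EDF+ annotation channels (`"EDF Annotations"`) are
#' dropped from the data array. All retained signal channels must share one
#' sampling rate.
#'
#' @param path Path to an `.edf` file.
#' @return An [eeg_record()] with `data` of shape
#'   `(n_records * samples_per_record, n_ch)`.
#' @seealso [write_edf()]
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  version <- read_ascii(con, 8L)
  if (!identical(version, "0")) {
    stop("malformed EDF header: unsupported version '", version, "'")
  }
  read_ascii(con, 80L)                       # patient id
  read_ascii(con, 80L)                       # recording id
  read_ascii(con, 8L)                        # start date
  read_ascii(con, 8L)                        # start time
  header_bytes <- num_field(read_ascii(con, 8L), "header size")
  read_ascii(con, 44L)                       # reserved (EDF+C marker)
  n_records <- num_field(read_ascii(con, 8L), "record count")
  duration <- num_field(read_ascii(con, 8L), "record duration")
  ns <- as.integer(num_field(read_ascii(con, 4L), "signal count"))
  if (ns < 1L) stop("malformed EDF header: no signals")
  if (duration <= 0) stop("malformed EDF header: non-positive record duration")

  sig_field <- function(width, n = ns) {
    vapply(seq_len(n), function(i) read_ascii(con, width), character(1))
  }
  labels <- sig_field(16L)
  sig_field(80L)                             # transducer
  sig_field(8L)                              # physical dimension
  phys_min <- as.numeric(sig_field(8L))
  phys_max <- as.numeric(sig_field(8L))
  dig_min <- as.numeric(sig_field(8L))
  dig_max <- as.numeric(sig_field(8L))
  if (anyNA(phys_min) || anyNA(phys_max) || anyNA(dig_min) || anyNA(dig_max)) {
    stop("malformed EDF header: non-numeric scaling field")
  }
  sig_field(80L)                             # prefiltering
  spr <- as.integer(as.numeric(sig_field(8L)))
  if (anyNA(spr) || any(spr < 1L)) {
    stop("malformed EDF header: invalid samples-per-record")
  }
  sig_field(32L)                             # reserved
  if (header_bytes != 256L + 256L * ns) {
    stop("malformed EDF header: header size field inconsistent with signal count")
  }

  spr_total <- sum(spr)
  if (n_records < 0) {
    # -1 means 'unknown'; infer from file size
    data_bytes <- file.size(path) - header_bytes
    n_records <- floor(data_bytes / (2L * spr_total))
  }
  n_records <- as.integer(n_records)
  if (n_records < 1L) stop("EDF file contains zero data records")

  keep <- which(labels != EDF_ANNOTATION_LABEL)
  if (length(keep) < 1L) stop("EDF file contains no signal channels")
  if (length(unique(spr[keep])) != 1L) {
    stop("retained signal channels have heterogeneous sampling rates")
  }
  if (any(dig_max[keep] <= dig_min[keep])) {
    stop("malformed EDF header: digital max <= digital min")
  }

  raw_vals <- readBin(con, integer(), n = n_records * spr_total, size = 2L,
                      signed = TRUE, endian = "little")
  if (length(raw_vals) < n_records * spr_total) {
    stop("malformed EDF file: data section truncated")
  }
  rec_mat <- matrix(raw_vals, nrow = spr_total, ncol = n_records)

  offsets <- c(0L, cumsum(spr))
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  off <- phys_min - dig_min * gain
  n_t <- n_records * spr[keep[1L]]
  data <- matrix(0, nrow = n_t, ncol = length(keep))
  for (j in seq_along(keep)) {
    ch <- keep[j]
    rows <- (offsets[ch] + 1L):(offsets[ch] + spr[ch])
    data[, j] <- as.vector(rec_mat[rows, , drop = FALSE]) * gain[ch] + off[ch]
  }

  fs <- spr[keep[1L]] / duration
  eeg_record(data, fs = fs, channel_names = labels[keep])
}

# format a number into at most `width` ASCII chars, parseable by as.numeric
fmt_num <- function(x, width = 8L) {
  for (d in 7:1) {
    s <- formatC(x, digits = d, format = "g", width = 1L)
    if (nchar(s) <= width && !is.na(suppressWarnings(as.numeric(s)))) return(s)
  }
  stop("cannot format value into EDF numeric field: ", x)
}

pad_field <- function(s, width) {
  s <- substr(s, 1L, width)
  formatC(s, width = -width, flag = " ")
}

#' Write an EDF file
#'
#' Emits a standard-conformant plain EDF (16-bit) file readable by
#' [read_edf()]. Physical minimum/maximum are set symmetrically from each
#' channel's data range, so the round-trip error is at most half a digital
#' quantization step. The record duration is 1 s, so `fs` must be a whole
#' number; if the number of samples is not a multiple of `fs`, the final
#' record is zero-padded (with a warning).
#'
#' @param record An [eeg_record()] with finite data.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  x <- record$data
  if (ncol(x) < 1L) stop("record has no channels")
  if (!all(is.finite(x))) stop("non-finite samples cannot be written to EDF")
  fs <- record$fs
  if (abs(fs - round(fs)) > 1e-9) {
    stop("write_edf uses 1 s records; `fs` must be a whole number of Hz")
  }
  spr <- as.integer(round(fs))
  n_t <- nrow(x)
  n_records <- as.integer(ceiling(n_t / spr))
  pad <- n_records * spr - n_t
  if (pad > 0L) {
    warning("padding final EDF record with ", pad, " zero sample(s)")
    x <- rbind(x, matrix(0, pad, ncol(x)))
  }
  ns <- ncol(x)

  pm_str <- character(ns)
  gain <- numeric(ns)
  dig <- matrix(0L, nrow(x), ns)
  for (ch in seq_len(ns)) {
    pm <- max(abs(x[, ch]))
    if (pm == 0) pm <- 1
    # 7 chars so the "-"-prefixed physical minimum also fits its 8-byte field
    s <- fmt_num(pm * (1 + 1e-6), width = 7L)
    while (as.numeric(s) < pm) s <- fmt_num(as.numeric(s) * (1 + 1e-3), width = 7L)
    pm_str[ch] <- s
    gain[ch] <- as.numeric(s) / 32767
    d <- round(x[, ch] / gain[ch])
    dig[, ch] <- as.integer(pmin(pmax(d, -32767), 32767))
  }

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  put <- function(s, width) writeChar(pad_field(s, width), con, nchars = width,
                                      eos = NULL)
  put("0", 8L)
  put("X X X X", 80L)
  put("Startdate X X X X", 80L)
  put("01.01.00", 8L)
  put("00.00.00", 8L)
  put(as.character(256L + 256L * ns), 8L)
  put("", 44L)
  put(as.character(n_records), 8L)
  put("1", 8L)
  put(as.character(ns), 4L)

  put_each <- function(vals, width) for (v in vals) put(v, width)
  put_each(record$channel_names, 16L)
  put_each(rep("", ns), 80L)
  put_each(rep("uV", ns), 8L)
  put_each(paste0("-", pm_str), 8L)
  put_each(pm_str, 8L)
  put_each(rep("-32767", ns), 8L)
  put_each(rep("32767", ns), 8L)
  put_each(rep("", ns), 80L)
  put_each(rep(as.character(spr), ns), 8L)
  put_each(rep("", ns), 32L)

  # records: for each record, each channel's block of spr int16 samples
  idx <- seq_len(spr)
  for (r in seq_len(n_records)) {
    rows <- (r - 1L) * spr + idx
    writeBin(as.integer(dig[rows, ]), con, size = 2L, endian = "little")
  }
  invisible(path)
}
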