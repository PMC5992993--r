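#' Read an electrode coordinate file
#'
#' Parses a whitespace- or comma-delimited text file with one electrode per
#' row: a label followed by three cartesian coordinates (arbitrary units).
#' A single header row is tolerated; blank lines and `#` comments are
#' skipped.
#'
#' @param path Path to the coordinate file.
#' @return An `electrode_layout`: a tibble with columns `label`, `x`, `y`,
#'   `z`.
#' @examples
#' f <- tempfile(fileext = ".xyz")
#' writeLines(c("Cz 0 0 1", "Oz 0 -1 0"), f)
#' read_xyz(f)
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("coordinate file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 1L) stop("coordinate file is empty")

  parse_row <- function(line) {
    fields <- strsplit(line, "[,[:space:]]+")[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 4L) {
      stop("coordinate row has fewer than 4 fields: '", line, "'")
    }
    xyz <- suppressWarnings(as.numeric(fields[2:4]))
    if (anyNA(xyz)) stop("non-numeric coordinate in row: '", line, "'")
    list(label = fields[[1]], x = xyz[1], y = xyz[2], z = xyz[3])
  }

  # tolerate one header row: first line whose coordinate fields do not parse
  first <- tryCatch(parse_row(lines[[1]]), error = function(e) NULL)
  if (is.null(first)) lines <- lines[-1L]
  rows <- lapply(lines, parse_row)
  out <- tibble::tibble(
    label = vapply(rows, `[[`, character(1), "label"),
    x = vapply(rows, `[[`, numeric(1), "x"),
    y = vapply(rows, `[[`, numeric(1), "y"),
    z = vapply(rows, `[[`, numeric(1), "z")
  )
  as_electrode_layout(out)
}

#' Coerce to an electrode layout
#'
#' @param x A data frame with columns `label`, `x`, `y`, `z`.
#' @return An `electrode_layout` tibble.
#' @export
as_electrode_layout <- function(x) {
  if (inherits(x, "electrode_layout")) return(x)
  x <- tibble::as_tibble(x)
  if (!all(c("label", "x", "y", "z") %in% names(x))) {
    stop("layout needs columns label, x, y, z")
  }
  if (nrow(x) < 2L) stop("layout needs at least 2 electrodes")
  if (anyDuplicated(x$label)) stop("layout labels must be unique")
  class(x) <- c("electrode_layout", class(x))
  x
}

#' Idealized microstate template topographies
#'
#' Builds four canonical reference topographies over an electrode layout,
#' used for non-interactive A-D ordering of clustered maps: A and B are the
#' two diagonal gradients, C is anterior-posterior, D is a radial
#' (center-weighted) pattern. Rows are zero-mean and unit-norm. These are
#' idealized geometric templates, not empirical group maps.
#'
#' @param layout An `electrode_layout`.
#' @return A numeric matrix `(4, n_ch)` with channel-name columns.
#' @export
template_maps <- function(layout) {
  layout <- as_electrode_layout(layout)
  u <- layout$x / max(abs(layout$x), 1e-12)
  v <- layout$y / max(abs(layout$y), 1e-12)
  tpl <- rbind(
    A = v - u,            # left-frontal to right-occipital diagonal
    B = v + u,            # right-frontal to left-occipital diagonal
    C = v,                # anterior-posterior axis
    D = -(u^2 + v^2)      # radial, center-positive
  )
  tpl <- tpl - rowMeans(tpl)
  tpl <- tpl / sqrt(rowSums(tpl^2))
  colnames(tpl) <- layout$label
  tpl
}
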