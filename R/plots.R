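# ggplot2 visualizations for the result objects.

#' Plot microstate maps as channel-by-map heat tiles
#'
#' @param object A `microstate_segmentation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.microstate_segmentation <- function(object, ...) {
  maps <- object$maps
  df <- tibble::tibble(
    map = factor(rep(0:(nrow(maps) - 1L), each = ncol(maps))),
    channel = factor(rep(colnames(maps), times = nrow(maps)),
                     levels = colnames(maps)),
    value = as.numeric(t(maps))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$map,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = "channel", y = "microstate map",
                  fill = "amplitude (a.u.)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a transition matrix
#'
#' @param object A `transition_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transition_model <- function(object, ...) {
  df <- tidy.transition_model(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$to),
                                   y = factor(.data$from),
                                   fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$prob)),
                       size = 3) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "to state", y = "from state",
                  fill = "P(to | from)") +
    ggplot2::theme_minimal()
}

#' Plot the autoinformation function with its surrogate band
#'
#' Empirical autoinformation (line and points), the analytic Markov
#' autoinformation (dashed), and the surrogate confidence band (ribbon),
#' on a log-scaled information axis.
#'
#' @param object A `microstate_aif`.
#' @param log_y Use a log10 information axis (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.microstate_aif <- function(object, log_y = TRUE, ...) {
  tbl <- object$table
  xvar <- if ("lag_ms" %in% names(tbl)) "lag_ms" else "lag"
  xlab <- if (xvar == "lag_ms") "lag (ms)" else "lag (samples)"
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data[[xvar]])) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$band_lo,
                                      ymax = .data$band_hi),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$I_markov),
                       linetype = "dashed", color = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$I_emp)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$I_emp), size = 0.8) +
    ggplot2::labs(x = xlab, y = "autoinformation I(k) (nats)") +
    ggplot2::theme_minimal()
  if (log_y) {
    floor_val <- max(min(tbl$I_emp[tbl$I_emp > 0], na.rm = TRUE) / 10,
                     1e-12)
    p <- p + ggplot2::scale_y_log10(
      limits = c(floor_val, NA), oob = scales_squish
    )
  }
  p
}

# minimal squish (avoid a scales dependency for one helper)
scales_squish <- function(x, range = c(0, 1), only.finite = TRUE) {
  x[which(x < range[1])] <- range[1]
  x[which(x > range[2])] <- range[2]
  x
}

#' Plot GFP with detected peaks
#'
#' @param record An [eeg_record()].
#' @param t_max Seconds of data to show; default 4.
#' @return A ggplot object.
#' @export
plot_gfp <- function(record, t_max = 4) {
  stopifnot(inherits(record, "eeg_record"))
  n <- min(nrow(record$data), ceiling(t_max * record$fs))
  g <- gfp(record$data[seq_len(n), , drop = FALSE])
  pk <- find_gfp_peaks(g)
  df <- tibble::tibble(time = (seq_len(n) - 1) / record$fs, gfp = g)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$gfp)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::geom_point(data = df[pk, ], color = "#b2182b", size = 1) +
    ggplot2::labs(x = "time (s)", y = "GFP (µV)") +
    ggplot2::theme_minimal()
}
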