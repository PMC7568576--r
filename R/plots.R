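#' Plot a scalogram
#'
#' Time-frequency heat map of the CWT magnitude on a log2 frequency
#' axis, drawn with the parula-style palette scalograms are commonly
#' shown in.
#'
#' @param object a `scalogram`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.scalogram <- function(object, ...) {
  df <- tibble(
    freq_hz = rep(object$frequencies_hz, times = length(object$times_s)),
    time_s = rep(object$times_s, each = length(object$frequencies_hz)),
    magnitude = as.vector(object$magnitude)
  )
  p128 <- parula_colors(128)
  pal <- grDevices::rgb(p128[, 1], p128[, 2], p128[, 3])
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$freq_hz,
                                   fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::scale_fill_gradientn(colours = pal) +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)",
                  fill = "|CWT|",
                  title = paste0(object$subject_id, " ", object$channel)) +
    ggplot2::theme_minimal()
}

#' Bar + Pareto plots of a selection summary
#'
#' One panel per category family (frequency band, statistic, signal
#' source): bars are selected-feature counts in descending order, the
#' line is the cumulative (Pareto) percentage.
#'
#' @param object a `selection_summary` from [summarize_selection()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.selection_summary <- function(object, ...) {
  df <- tidy(object)
  df$category <- factor(df$category, levels = unique(df$category))
  scale <- max(df$count, 1)
  ggplot2::ggplot(df, ggplot2::aes(.data$category)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count), fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$pareto_pct / 100 * scale,
                                    group = 1), colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$pareto_pct / 100 * scale),
                        colour = "firebrick") +
    ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(~ . / scale * 100,
                                   name = "cumulative %")) +
    ggplot2::facet_wrap(~family, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "selected features") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Confusion-matrix heat map of an evaluation report
#'
#' @param object an `evaluation_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  names(df) <- c("truth", "pred", "n")
  ggplot2::ggplot(df, ggplot2::aes(.data$pred, .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_gradient(low = "grey30", high = "steelblue") +
    ggplot2::labs(
      title = sprintf("%s / %s: accuracy %.3f", object$scheme,
                      object$model_family, object$accuracy)) +
    ggplot2::theme_minimal()
}
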