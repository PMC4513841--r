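#' Plot replicate stringency frequencies
#'
#' Log10-scale point-and-error-bar plot of stringency frequencies per
#' cassette/strain: the bar is the mean of log-transformed replicate
#' values (geometric mean) and the error bars its log10 standard
#' deviation, the conventional presentation for selection-stringency
#' comparisons.
#'
#' @param data Data frame with columns `label` (cassette/strain) and
#'   `frequency` (one row per replicate, all > 0).
#' @return A ggplot object.
#' @export
plot_stringency <- function(data) {
  data <- as_tibble(data)
  if (!all(c("label", "frequency") %in% names(data))) {
    abort("`data` needs columns `label` and `frequency`.")
  }
  summ <- data |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(aggregate_replicates(.data$frequency),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$label,
                                     y = .data$geometric_mean)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = 10^(log10(.data$geometric_mean) - .data$log10_sd),
                   ymax = 10^(log10(.data$geometric_mean) + .data$log10_sd)),
      width = 0.2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "stringency frequency") +
    ggplot2::theme_minimal()
}

#' @describeIn escape_rate_chain Interval plot of every stage of the
#'   theoretical escape-rate chain on a log10 axis.
#' @param object An `escape_rate_chain` tibble.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.escape_rate_chain <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::mutate(stage = factor(.data$stage, levels = rev(.data$stage)),
                  low = pmax(.data$low, .Machine$double.xmin))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$stage)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$low, xmax = .data$high), height = 0.25) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "rate per generation", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn presence_matrix Coverage heat map with presence calls
#'   outlined.
#' @param object A `presence_matrix` tibble.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.presence_matrix <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$genome, y = .data$gene,
                               fill = .data$coverage)) +
    ggplot2::geom_tile(ggplot2::aes(colour = .data$present),
                       linewidth = 0.4) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black",
                                            `FALSE` = "grey80")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
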