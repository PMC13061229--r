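#' Box plot of daytime vs evening apparency per sound
#'
#' Mirrors the diurnal-variability summary figure: for each sound, paired
#' box-and-whisker distributions of per-participant apparency in the daytime
#' (segments A and C) and evening (segments B and D) scopes.
#'
#' @param pairs Output of [diurnal_split()].
#' @return A ggplot object.
#' @export
plot_diurnal_apparency <- function(pairs) {
  long <- tidyr::pivot_longer(pairs, c("daytime_pct", "evening_pct"),
                              names_to = "daypart", values_to = "apparency_pct")
  long$daypart <- factor(sub("_pct", "", long$daypart),
                         levels = c("daytime", "evening"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sound_code,
                                     y = .data$apparency_pct,
                                     fill = .data$daypart)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8),
                          outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = "Apparency (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of OR values with classification thresholds
#'
#' @param measurements Scored OR tibble.
#' @param threshold Threshold drawn as vertical lines.
#' @return A ggplot object.
#' @export
plot_or_distribution <- function(measurements, threshold = 2) {
  m <- dplyr::filter(measurements, !is.na(.data$or_value))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$or_value)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey60", colour = "grey30") +
    ggplot2::geom_vline(xintercept = c(-threshold, threshold),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "OR value", y = "Presentations") +
    ggplot2::theme_minimal()
}

#' @method autoplot apparency_rct
#' @export
autoplot.apparency_rct <- function(object, ...) {
  # the fitted object carries per-sound summaries; show the paired-test
  # mean differences (daytime - evening sign convention)
  ggplot2::ggplot(object$diurnal,
                  ggplot2::aes(x = .data$sound_code, y = .data$mean_diff)) +
    ggplot2::geom_col(fill = "grey50") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "Mean apparency difference (daytime - evening, %)") +
    ggplot2::theme_minimal()
}

#' @method autoplot apparency_run
#' @export
autoplot.apparency_run <- function(object, ...) {
  pairs <- suppressMessages(diurnal_split(
    dplyr::filter(object$or_table, .data$period == 2,
                  .data$sound_code %in% object$screen$retained)
  ))
  plot_diurnal_apparency(pairs)
}
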