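#' Plot a fitted calibration curve over calibration observations
#'
#' @param object A `pool_calibration` fit.
#' @param data Optional calibration observations (columns `fir`,
#'   `expected_freq`) drawn as points under the curve.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pool_calibration <- function(object, data = NULL, ...) {
  grid <- tibble(fir = seq(0, 1, length.out = 201))
  grid$freq_b <- predict_frequency(object, grid$fir)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$fir, y = .data$freq_b))
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(
      data = data, ggplot2::aes(x = .data$fir, y = .data$expected_freq),
      alpha = 0.25, colour = "grey40"
    )
  }
  p + ggplot2::geom_line(colour = "#2166AC", linewidth = 1) +
    ggplot2::labs(x = "Fluorescence intensity ratio (FIR)",
                  y = "Allele-B frequency",
                  title = "Logit-link FIR calibration curve")
}

#' Plot MAE by expected-frequency bin
#'
#' @param object An `mae_report` from [mean_absolute_error()].
#' @param ... Ignored.
#' @return A ggplot of the per-bin mean absolute error.
#' @export
autoplot.mae_report <- function(object, ...) {
  ggplot2::ggplot(object$breakdown,
                  ggplot2::aes(x = .data$bin, y = .data$mae)) +
    ggplot2::geom_col(fill = "#2166AC") +
    ggplot2::labs(x = "Expected allele-B frequency bin",
                  y = "Mean absolute error") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot sampling-error bounds against allele frequency
#'
#' Visualizes exact Clopper-Pearson sampling bounds (one ribbon per
#' individuals-by-replicates design) as a function of the bulk allele
#' frequency.
#'
#' @param table Output of [sampling_table()].
#' @return A ggplot.
#' @export
plot_sampling_bounds <- function(table) {
  assert_columns(table, c("freq", "n_individuals", "n_replicates",
                          "lower", "upper"), "table")
  table <- mutate(table, design = sprintf(
    "%d individuals x %d replicate(s)", .data$n_individuals, .data$n_replicates))
  ggplot2::ggplot(table, ggplot2::aes(x = .data$freq)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper,
                                      fill = .data$design), alpha = 0.25) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "Bulk allele-B frequency",
                  y = "95% sampling bounds", fill = NULL)
}
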