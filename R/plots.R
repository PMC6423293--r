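#' Plot per-treatment mutation rates with Poisson intervals
#'
#' @param object A `treatment_rates` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot treatment_rates
#' @export
autoplot.treatment_rates <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$treatment,
                                    y = .data$mean_rate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = NULL,
                  y = "mutation rate (per site per generation)") +
    ggplot2::theme_minimal()
}

#' Plot a mutation spectrum
#'
#' @param spectrum Tibble from [mutation_spectrum()].
#' @return A ggplot.
#' @export
plot_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum, ggplot2::aes(x = .data$spectrum, y = .data$n,
                                         fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mutation class (pyrimidine-first)", y = "count",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the filter cascade survival curve
#'
#' @param report Tibble `stage, sites` from [run_ma_pipeline()] (the
#'   `report` element).
#' @return A ggplot.
#' @export
plot_filter_report <- function(report) {
  report <- report %>% mutate(stage = factor(.data$stage,
                                             levels = .data$stage))
  ggplot2::ggplot(report, ggplot2::aes(x = .data$stage, y = .data$sites,
                                       group = 1)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "variant sites remaining") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
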