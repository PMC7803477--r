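#' Device versus self-report agreement scatter panels
#'
#' One panel per analogous measure pair, device on the x axis and
#' self-report on the y axis, with the identity line where the two are
#' on the same scale (overall activity is steps/d versus MET-h/wk, so
#' no identity line is meaningful there).
#'
#' @param data Observation-level data (typically the rank-1 comparative
#'   set).
#' @return A ggplot object.
#' @export
plot_agreement <- function(data) {
  d <- data
  d$fitbit_moderate_h <- d$fitbit_moderate_time / 60
  d$fitbit_vigorous_h <- d$fitbit_vigorous_time / 60
  d$ipaq_moderate_h <- d$ipaq_moderate_time / 60
  d$ipaq_vigorous_h <- d$ipaq_vigorous_time / 60
  spec <- battery_measures()
  long <- pmap(spec, function(measure, fitbit, ipaq, unit_mode) {
    tibble(measure = measure, fitbit = d[[fitbit]], ipaq = d[[ipaq]],
           same_units = measure != "overall")
  }) |> list_rbind()
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fitbit, y = .data$ipaq)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(
      data = ~ dplyr::filter(.x, .data$same_units) |>
        dplyr::distinct(.data$measure),
      ggplot2::aes(intercept = 0, slope = 1), linetype = "dashed"
    ) +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::labs(x = "Device measure", y = "Self-report measure")
}

#' Forest plot of the model battery coefficients
#'
#' Activity coefficients (BMI change per predictor unit) with 95%
#' cluster-robust confidence intervals, device versus self-report side
#' by side, faceted by measure and adjustment tier.
#'
#' @param object A `model_battery`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot model_battery
#' @export
autoplot.model_battery <- function(object, ...) {
  td <- tidy(object)
  td$model_mode <- factor(td$model_mode,
                          c("separate_fitbit", "separate_ipaq", "combined"))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$instrument,
                                   colour = .data$model_mode)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      position = ggplot2::position_dodge(width = 0.5), size = 0.3
    ) +
    ggplot2::facet_grid(measure ~ tier, scales = "free_x") +
    ggplot2::labs(x = "BMI difference per predictor unit (kg/m²)",
                  y = NULL, colour = "model")
}

#' Plot BMI by ordered activity category
#'
#' Group means with SD bars from a [trend_test()] result.
#'
#' @param object A `trend_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trend_test
#' @export
autoplot.trend_test <- function(object, ...) {
  g <- object$groups
  ggplot2::ggplot(g, ggplot2::aes(x = .data$score, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = g$score, labels = g$group) +
    ggplot2::labs(x = "activity category", y = "outcome mean ± SD")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write weekly measures as delimited text
#'
#' @param weeks A weekly-measures tibble (e.g. from [summarize_week()]
#'   rows or the `fitbit_*` columns of an observation table).
#' @param path Output file path (CSV).
#' @return `path`, invisibly.
#' @export
write_week_measures <- function(weeks, path) {
  readr::write_csv(weeks, path)
  invisible(path)
}
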