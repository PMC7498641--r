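#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Cost-effectiveness plane of PSA samples
#'
#' Scatter of incremental QALYs against incremental costs, one point per
#' probabilistic draw, with dashed willingness-to-pay rays through the
#' origin. Points below a ray are cost-effective at that threshold.
#'
#' @param object A `psa_result` from [run_psa()].
#' @param lambdas Thresholds (£/QALY) to draw; defaults to the CEAC grid.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psa_result <- function(object, lambdas = object$ceac$lambda, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(x = .data$delta_qalys, y = .data$delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.25, size = 0.7, colour = "#2166ac") +
    ggplot2::geom_abline(
      data = data.frame(slope = unique(lambdas)),
      ggplot2::aes(slope = .data$slope, intercept = 0),
      linetype = "dashed", colour = "grey30") +
    ggplot2::labs(
      x = "Incremental QALYs", y = "Incremental cost (£)",
      title = sprintf("Cost-effectiveness plane (%s skin tone)",
                      object$subgroup),
      subtitle = sprintf("%d PSA samples, seed %d", object$n_samples,
                         object$master_seed)) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve
#'
#' @param psa A `psa_result`, or a tibble with columns `lambda` and
#'   `probability_ce` (optionally `subgroup`).
#' @param lambdas Dense lambda grid used when `psa` is a `psa_result`
#'   (default 0 to £60,000 in £500 steps).
#' @return A ggplot.
#' @export
plot_ceac <- function(psa, lambdas = seq(0, 60000, by = 500)) {
  df <- if (inherits(psa, "psa_result"))
    ceac(psa$samples, lambdas) else tibble::as_tibble(psa)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda,
                                        y = .data$probability_ce))
  if ("subgroup" %in% names(df))
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$subgroup))
  else
    p <- p + ggplot2::geom_line(colour = "#2166ac")
  p +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (£/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Tornado diagram of univariate sweeps
#'
#' Horizontal bars spanning the net-monetary-benefit range as each
#' parameter moves between its 2.5th and 97.5th percentiles, widest bar on
#' top.
#'
#' @param object A `tornado_result` from [tornado()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tornado_result <- function(object, ...) {
  df <- dplyr::mutate(object,
    parameter = factor(.data$parameter,
                       levels = rev(.data$parameter[order(
                         -abs(.data$nmb_upper - .data$nmb_lower))])),
    lo = pmin(.data$nmb_lower, .data$nmb_upper),
    hi = pmax(.data$nmb_lower, .data$nmb_upper))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$lo, xend = .data$hi, yend = .data$parameter),
      linewidth = 4, colour = "#2166ac", alpha = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Net monetary benefit (£)", y = NULL,
                  title = "Univariate sensitivity (tornado)") +
    ggplot2::theme_minimal()
}
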