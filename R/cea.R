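#' Incremental cost-effectiveness comparison of two arms
#'
#' Deltas are intervention minus comparator, always computed from unrounded
#' internals. Status follows standard CEA conventions: `dominant` when the
#' intervention is cheaper and more effective, `dominated` when dearer and
#' less effective, `zero_increment` when both deltas vanish, otherwise
#' `icer_defined` with `icer = delta_cost / delta_qalys`. An ICER in the
#' cheaper-and-less-effective quadrant is reported with its status rather
#' than as a bare ratio, because bare negative ICERs are ambiguous.
#'
#' @param comparator,intervention `strategy_outcome` objects from
#'   [evaluate_arm()], or bare lists with `expected_cost` and
#'   `expected_qalys`.
#' @return A one-row tibble of class `cea_result` with columns
#'   `comparator_cost`, `comparator_qalys`, `intervention_cost`,
#'   `intervention_qalys`, `delta_cost`, `delta_qalys`, `icer`, `status`.
#' @examples
#' cea_compare(list(expected_cost = 2.85, expected_qalys = 3.333224),
#'             list(expected_cost = 12.14, expected_qalys = 3.333706))
#' @export
cea_compare <- function(comparator, intervention) {
  dc <- intervention$expected_cost - comparator$expected_cost
  dq <- intervention$expected_qalys - comparator$expected_qalys
  status <- if (dc < 0 && dq > 0) "dominant"
    else if (dc > 0 && dq < 0) "dominated"
    else if (dc == 0 && dq == 0) "zero_increment"
    else "icer_defined"
  icer <- if (status == "icer_defined" && dq != 0) dc / dq else NA_real_
  if (status == "icer_defined" && dq == 0) status <- "zero_increment"
  out <- tibble::new_tibble(list(
    comparator_cost = comparator$expected_cost,
    comparator_qalys = comparator$expected_qalys,
    intervention_cost = intervention$expected_cost,
    intervention_qalys = intervention$expected_qalys,
    delta_cost = dc, delta_qalys = dq, icer = icer, status = status),
    nrow = 1L)
  class(out) <- c("cea_result", class(out))
  out
}

#' Net monetary benefit at a willingness-to-pay threshold
#'
#' `NMB = lambda * delta_qalys - delta_cost`. Positive NMB at the threshold
#' means the intervention is cost-effective; a defined ICER is exactly the
#' lambda at which NMB crosses zero.
#'
#' @param result A `cea_result` (or anything with `delta_cost` and
#'   `delta_qalys`).
#' @param lambda Willingness to pay (£/QALY), `>= 0` (vectorised).
#' @return Net monetary benefit in £.
#' @export
nmb <- function(result, lambda) {
  if (any(lambda < 0)) stop("lambda must be >= 0", call. = FALSE)
  lambda * result$delta_qalys - result$delta_cost
}

#' Cost-effectiveness acceptability curve from PSA samples
#'
#' For each willingness-to-pay value, the proportion of probabilistic
#' samples with positive net monetary benefit.
#'
#' @param samples Data frame with columns `delta_cost` and `delta_qalys`,
#'   one row per PSA draw.
#' @param lambdas Numeric grid of willingness-to-pay values (£/QALY).
#' @return Tibble with columns `lambda` and `probability_ce`.
#' @export
ceac <- function(samples, lambdas = c(20000, 30000)) {
  if (nrow(samples) < 1) stop("ceac requires at least one sample", call. = FALSE)
  purrr::map_dfr(lambdas, function(l) {
    tibble::tibble(
      lambda = l,
      probability_ce = mean(l * samples$delta_qalys - samples$delta_cost > 0))
  })
}

#' Format an ICER for reporting
#'
#' Rounds defined ICERs to the nearest pound and renders dominance statuses
#' as the literal strings used in published tables.
#'
#' @param result A `cea_result` (one or more rows).
#' @return Character vector, e.g. `"19,295"` or `"Dominant"`.
#' @export
format_icer <- function(result) {
  vapply(seq_along(result$status), function(i) {
    switch(result$status[i],
      dominant = "Dominant",
      dominated = "Dominated",
      zero_increment = "-",
      icer_defined = formatC(round(result$icer[i]), format = "d",
                             big.mark = ","))
  }, character(1))
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>\n")
  lab <- if ("subgroup" %in% names(x)) paste0(x$subgroup, ": ") else ""
  cat(sprintf("  %sdC = %.4f, dQ = %.6g, ICER = %s (%s)\n",
              lab, x$delta_cost, x$delta_qalys, format_icer(x), x$status),
      sep = "")
  invisible(x)
}
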