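#' Supplement acquisition cost over a supplementation period
#'
#' Pro-rates the pack price over the days each pack covers:
#' `pack_price * duration_days / days_per_pack`, unrounded (rounding happens
#' only at the report layer). With the Healthy Start prices this gives £3.57
#' per pregnancy (£0.74, 56-day packs, 270 days) and £9.91 per child-year
#' (£1.52, 56-day packs, 365 days; published tables print £9.90).
#'
#' @param pack_price Price per pack (£).
#' @param days_per_pack Days one pack covers, `> 0`.
#' @param duration_days Days of supplementation, `>= 0`.
#' @return Cost in £ (vectorised).
#' @export
supplement_cost <- function(pack_price, days_per_pack, duration_days) {
  if (any(pack_price < 0) || any(duration_days < 0))
    stop("prices and durations must be non-negative", call. = FALSE)
  if (any(days_per_pack <= 0)) stop("days_per_pack must be > 0", call. = FALSE)
  pack_price * duration_days / days_per_pack
}

#' Total treatment cost from tariff line items
#'
#' Sums `unit_price * quantity` over the line items of one or more cases.
#' When `data` carries a `case_id` column the sum is returned per case.
#'
#' @param data Data frame of tariff line items with columns `unit_price` and
#'   `quantity`, optionally `case_id`.
#' @return Tibble with column `total_cost` (one row, or one per `case_id`).
#' @export
rickets_treatment_cost <- function(data) {
  if (nrow(data) == 0)
    return(tibble::tibble(total_cost = 0))
  if (any(data$unit_price < 0) || any(data$quantity < 0))
    stop("unit_price and quantity must be non-negative", call. = FALSE)
  if ("case_id" %in% names(data)) {
    data |>
      dplyr::group_by(.data$case_id) |>
      dplyr::summarise(total_cost = sum(.data$unit_price * .data$quantity),
                       .groups = "drop")
  } else {
    tibble::tibble(total_cost = sum(data$unit_price * data$quantity))
  }
}

#' Present value of a per-period payment stream
#'
#' `sum(x_t / (1 + rate)^(t + offset))` with the offset set by the timing
#' convention: `"start"` (payments at the start of each period, offset 0,
#' the default and the convention used for utility accrual), `"mid"`
#' (offset 0.5, half-cycle correction) or `"end"` (offset 1).
#'
#' @param stream Numeric vector of per-period amounts (period 1 first).
#' @param rate Per-period discount rate, `>= 0`.
#' @param timing `"start"`, `"mid"` or `"end"`.
#' @return Present value (scalar).
#' @export
discount <- function(stream, rate, timing = c("start", "mid", "end")) {
  timing <- match.arg(timing)
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  offset <- c(start = 0, mid = 0.5, end = 1)[[timing]]
  t <- seq_along(stream) - 1
  sum(stream / (1 + rate)^(t + offset))
}

# per-period discount factors, start-of-period timing
.disc_factors <- function(n, rate, timing = "start") {
  offset <- c(start = 0, mid = 0.5, end = 1)[[timing]]
  (1 + rate)^-(seq_len(n) - 1 + offset)
}

#' Discounted intervention cost per child
#'
#' Present value of the payer's cost of offering free supplements to one
#' child of the target cohort: the child's annual supplement cost over the
#' programme horizon and the mother's pregnancy supplement cost (incurred at
#' time zero), each multiplied by the payer-coverage fraction, plus the
#' child's share of the administration/promotion budget.
#'
#' The coverage policy decides whose supplements the payer is costed for:
#' `"incremental"` (default) costs only the uptake increase the programme
#' induces; `"all-supplemented"` costs baseline uptake plus the increase;
#' `"universal"` costs the whole cohort.
#'
#' @param child_annual_cost £ per child-year of supplements (e.g.
#'   [supplement_cost()] over 365 days).
#' @param pregnancy_cost £ per supplemented pregnancy.
#' @param uptake_increase_child,uptake_increase_woman Programme-induced
#'   uptake increases (proportions).
#' @param uptake_baseline_child,uptake_baseline_woman Baseline uptake
#'   (proportions); used by the non-default coverage policies.
#' @param admin_budget_per_year Administration budget (£/year), spread over
#'   `target_population` children.
#' @param target_population Number of children the budget is spread over.
#' @param horizon_years Programme duration in years (default 4).
#' @param discount_rate Annual discount rate (default 0.035).
#' @param coverage `"incremental"`, `"all-supplemented"` or `"universal"`.
#' @param timing Discount timing convention, see [discount()].
#' @return £ per child (present value).
#' @examples
#' # undiscounted: 39.60 * 0.20 + 3.57 * 0.17 + 40000 / 36413 = 9.63
#' intervention_cost_per_child(9.90, 3.57, 0.20, 0.17,
#'                             admin_budget_per_year = 10000,
#'                             target_population = 36413,
#'                             discount_rate = 0)
#' @export
intervention_cost_per_child <- function(child_annual_cost, pregnancy_cost,
                                        uptake_increase_child,
                                        uptake_increase_woman,
                                        uptake_baseline_child = 0,
                                        uptake_baseline_woman = 0,
                                        admin_budget_per_year = 10000,
                                        target_population = 36413,
                                        horizon_years = 4,
                                        discount_rate = 0.035,
                                        coverage = c("incremental",
                                                     "all-supplemented",
                                                     "universal"),
                                        timing = "start") {
  coverage <- match.arg(coverage)
  if (target_population <= 0)
    stop("target_population must be > 0", call. = FALSE)
  props <- c(uptake_increase_child, uptake_increase_woman,
             uptake_baseline_child, uptake_baseline_woman)
  if (any(props < 0 | props > 1))
    stop("uptake proportions must be in [0, 1]", call. = FALSE)
  cover_child <- switch(coverage,
    incremental = uptake_increase_child,
    `all-supplemented` = uptake_baseline_child + uptake_increase_child,
    universal = 1)
  cover_woman <- switch(coverage,
    incremental = uptake_increase_woman,
    `all-supplemented` = uptake_baseline_woman + uptake_increase_woman,
    universal = 1)
  annuity <- sum(.disc_factors(horizon_years, discount_rate, timing))
  child_annual_cost * cover_child * annuity +
    pregnancy_cost * cover_woman +
    admin_budget_per_year * annuity / target_population
}
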