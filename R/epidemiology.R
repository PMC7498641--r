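#' Annual rickets risk and incidence rate from case counts and census
#' denominators
#'
#' The annual risk for a subgroup is the average number of cases per year of
#' the observation window divided by the census count of children at risk:
#' `annual_risk = (cases_total / window_years) / population_at_risk`. The
#' cumulative risk over the 4-year eligibility horizon uses independent-year
#' compounding `1 - (1 - p)^4` by default; the linear approximation `4p` is
#' available via `cumulative = "linear"`.
#'
#' @param data Data frame with columns `subgroup`, `cases_total`,
#'   `window_years`, `population_at_risk` (one row per subgroup).
#' @param cumulative `"compound"` (default) or `"linear"` 4-year risk.
#' @return The input tibble with added columns `annual_risk`, `per_100k`
#'   (`annual_risk * 1e5`), and `cumulative_4yr`.
#' @examples
#' incidence_rates(data.frame(subgroup = "light", cases_total = 2,
#'                            window_years = 6, population_at_risk = 17344))
#' @export
incidence_rates <- function(data, cumulative = c("compound", "linear")) {
  cumulative <- match.arg(cumulative)
  req <- c("subgroup", "cases_total", "window_years", "population_at_risk")
  missing <- setdiff(req, names(data))
  if (length(missing))
    stop("incidence_rates: missing columns ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(data$cases_total < 0)) stop("cases_total must be >= 0", call. = FALSE)
  if (any(data$window_years <= 0)) stop("window_years must be > 0", call. = FALSE)
  if (any(data$population_at_risk <= 0))
    stop("population_at_risk must be > 0", call. = FALSE)
  dplyr::mutate(
    tibble::as_tibble(data),
    annual_risk = (.data$cases_total / .data$window_years) /
      .data$population_at_risk,
    per_100k = .data$annual_risk * 1e5,
    cumulative_4yr = if (cumulative == "compound")
      1 - (1 - .data$annual_risk)^4 else pmin(4 * .data$annual_risk, 1))
}

#' Wilson score confidence interval for a proportion
#'
#' Closed-form Wilson score interval for `k` successes out of `n` trials, the
#' method that reproduces the published 95% CI for the proportion of rickets
#' cases with onset before 48 months (54/57 -> 0.86-0.98). The
#' Clopper-Pearson exact interval is offered as an alternative.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param level Confidence level in (0, 1), default 0.95.
#' @param method `"wilson"` (default) or `"clopper-pearson"`.
#' @return Tibble with columns `estimate`, `lower`, `upper`.
#' @export
onset_proportion_ci <- function(k, n, level = 0.95,
                                method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  stopifnot(k >= 0, k <= n, n >= 1)
  if (level <= 0 || level >= 1)
    stop("level must be strictly in (0, 1)", call. = FALSE)
  phat <- k / n
  if (method == "wilson") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    denom <- 1 + z^2 / n
    centre <- phat + z^2 / (2 * n)
    half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2))
    lower <- (centre - half) / denom
    upper <- (centre + half) / denom
  } else {
    alpha <- 1 - level
    lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
    upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  }
  tibble::tibble(estimate = phat, lower = lower, upper = upper)
}

#' Apply an odds ratio to a baseline risk
#'
#' Converts the probability to odds, multiplies by the odds ratio, and
#' converts back: `p' = OR * p / (1 - p + OR * p)`. This is how the
#' intervention's effect on rickets incidence (OR 0.41, covering pre- and
#' post-natal supplementation as a single effect) is applied to each
#' subgroup's annual risk.
#'
#' @param baseline_risk Probability in \verb{[0, 1)} (vectorised).
#' @param or_effect Odds ratio, `> 0`.
#' @return Adjusted probability.
#' @examples
#' apply_or(0.5, 0.41)
#' @export
apply_or <- function(baseline_risk, or_effect) {
  if (any(or_effect <= 0)) stop("or_effect must be > 0", call. = FALSE)
  if (any(baseline_risk < 0 | baseline_risk > 1))
    stop("baseline_risk must be in [0, 1]", call. = FALSE)
  if (any(baseline_risk == 1 & or_effect != 1))
    stop("baseline_risk = 1 has undefined odds under OR != 1", call. = FALSE)
  or_effect * baseline_risk / (1 - baseline_risk + or_effect * baseline_risk)
}
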