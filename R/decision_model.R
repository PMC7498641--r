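#' Health-state parameters for the decision tree
#'
#' Bundles the health-state inputs of the two-stage model. Stage 1 (ages
#' 0-3) uses the rickets utility and duration; stage 2 (the lifetime
#' scenario) additionally uses the lifelong-complication and vitamin D
#' deficiency channels. The base case fixes `complication_probability = 0`
#' (no lifelong complications over the 4-year horizon).
#'
#' `complication_annual_cost` and `deficiency_annual_cost` have no published
#' values (expert-elicited in the source analysis); the defaults of £500/year
#' and £0/year are synthetic stand-ins. Deficiency prevalence defaults to
#' 0.23, the background prevalence of vitamin D deficiency reported for
#' England and Wales; because deficiency is assumed to return to this
#' baseline in both arms it cancels from every incremental result.
#'
#' @param rickets_utility Absolute utility while in the rickets state.
#' @param rickets_duration Years spent in the rickets state after onset
#'   (fractional years allowed; the final part-year is pro-rated).
#' @param complication_probability Probability a rickets case develops
#'   lifelong complications (scenario analysis only; 0 in the base case).
#' @param complication_disutility Lifelong utility decrement for complication
#'   sufferers.
#' @param complication_annual_cost Annual management cost (£) for
#'   complication sufferers, accrued in stage 2 (synthetic default).
#' @param deficiency_prevalence Population share vitamin D deficient in
#'   stage 2 (both arms).
#' @param deficiency_disutility Utility decrement for deficient individuals
#'   from `deficiency_onset_age` on.
#' @param deficiency_onset_age Age (years) at which the deficiency
#'   disutility begins.
#' @param deficiency_annual_cost Annual management cost (£) for deficient
#'   individuals in stage 2.
#' @param mortality_rr Relative risk on all-cause mortality for deficient
#'   individuals from `mortality_onset_age` on.
#' @param mortality_onset_age Age (years) from which the mortality RR
#'   applies.
#' @return A list of class `health_params`.
#' @export
health_params <- function(rickets_utility = 0.621,
                          rickets_duration = 2,
                          complication_probability = 0,
                          complication_disutility = 0.05,
                          complication_annual_cost = 500,
                          deficiency_prevalence = 0.23,
                          deficiency_disutility = 0.002,
                          deficiency_onset_age = 67.04,
                          deficiency_annual_cost = 0,
                          mortality_rr = 1.05,
                          mortality_onset_age = 76.92) {
  h <- list(rickets_utility = rickets_utility,
            rickets_duration = rickets_duration,
            complication_probability = complication_probability,
            complication_disutility = complication_disutility,
            complication_annual_cost = complication_annual_cost,
            deficiency_prevalence = deficiency_prevalence,
            deficiency_disutility = deficiency_disutility,
            deficiency_onset_age = deficiency_onset_age,
            deficiency_annual_cost = deficiency_annual_cost,
            mortality_rr = mortality_rr,
            mortality_onset_age = mortality_onset_age)
  stopifnot(rickets_utility >= 0, rickets_utility <= 1,
            rickets_duration >= 0,
            complication_probability >= 0, complication_probability <= 1,
            complication_disutility >= 0, complication_disutility <= 1,
            deficiency_prevalence >= 0, deficiency_prevalence <= 1,
            deficiency_disutility >= 0, deficiency_disutility <= 1,
            deficiency_onset_age >= 0, mortality_onset_age >= 0,
            mortality_rr > 0)
  structure(h, class = "health_params")
}

#' Model evaluation settings
#'
#' @param discount_rate Annual discount rate applied to both costs and QALYs
#'   (NICE reference-case default 3.5%).
#' @param gender_mix Proportion male in the cohort used for the baseline
#'   utility mixture (default 0.5).
#' @param timing Cycle accrual convention: `"start"` (default), `"mid"`
#'   (half-cycle correction) or `"end"`.
#' @param utility_form `"age_squared"` evaluates the published EQ-5D-3L
#'   baseline algorithm exactly as printed
#'   (`0.950857 - 0.000259 * age^2 + 0.021213 * gender`, clipped to
#'   \verb{[0, 1]}); `"population_norm"` substitutes the conventional UK
#'   population-norm regression with linear and quadratic age terms, which
#'   stays plausible at old ages.
#' @param horizon_years Stage-1 horizon in years (default 4).
#' @param max_age Terminal age for the lifetime scenario (default 100).
#' @param lambda_grid Willingness-to-pay values (£/QALY) for CEAC and NMB
#'   summaries (default 20,000 and 30,000).
#' @return A list of class `cea_config`.
#' @export
cea_config <- function(discount_rate = 0.035,
                       gender_mix = 0.5,
                       timing = c("start", "mid", "end"),
                       utility_form = c("age_squared", "population_norm"),
                       horizon_years = 4,
                       max_age = 100,
                       lambda_grid = c(20000, 30000)) {
  stopifnot(discount_rate >= 0, discount_rate < 1,
            gender_mix >= 0, gender_mix <= 1,
            horizon_years >= 1, max_age > horizon_years)
  structure(list(discount_rate = discount_rate, gender_mix = gender_mix,
                 timing = match.arg(timing),
                 utility_form = match.arg(utility_form),
                 horizon_years = horizon_years, max_age = max_age,
                 lambda_grid = lambda_grid),
            class = "cea_config")
}

#' Age- and sex-adjusted baseline utility
#'
#' Evaluates the UK EQ-5D-3L population baseline algorithm
#' `U = 0.950857 - 0.000259 * age^2 + 0.021213 * gender` (gender = 1 male,
#' 0 female), clipped to \verb{[0, 1]}. The printed quadratic-only form drives
#' utility to zero around age 62 and is therefore implemented exactly but
#' clipped; `form = "population_norm"` substitutes the standard UK norm
#' regression `0.9508566 + 0.0212126 * male - 0.0002587 * age -
#' 0.0000332 * age^2` for users who want plausible old-age utilities.
#'
#' @param age Age in years, `>= 0` (vectorised).
#' @param gender 1 for male, 0 for female (vectorised).
#' @param form `"age_squared"` (printed algorithm, default) or
#'   `"population_norm"`.
#' @return Utility in \verb{[0, 1]}.
#' @examples
#' baseline_utility(0, 0)  # 0.950857
#' baseline_utility(0, 1)  # 0.972070
#' @export
baseline_utility <- function(age, gender, form = c("age_squared",
                                                   "population_norm")) {
  form <- match.arg(form)
  if (any(age < 0)) stop("age must be >= 0", call. = FALSE)
  u <- switch(form,
    age_squared = 0.950857 - 0.000259 * age^2 + 0.021213 * gender,
    population_norm = 0.9508566 + 0.0212126 * gender - 0.0002587 * age -
      0.0000332 * age^2)
  pmin(pmax(u, 0), 1)
}

# gender-mixed baseline utility at a given age
.baseline_mixed <- function(age, config) {
  config$gender_mix * baseline_utility(age, 1, config$utility_form) +
    (1 - config$gender_mix) * baseline_utility(age, 0, config$utility_form)
}

#' Stylised synthetic life table
#'
#' The published analysis names no life table; this bundled stand-in is a
#' stylised Gompertz-type schedule (elevated infant mortality, low childhood
#' mortality, exponential increase in adulthood) clearly labelled synthetic.
#' Supply a real national life table as a data frame with columns `age` and
#' `qx` wherever one is available.
#'
#' @param max_age Last age covered (exclusive upper bound of the model).
#' @return Tibble with columns `age` (0, 1, ...) and `qx` (annual probability
#'   of death).
#' @export
synthetic_life_table <- function(max_age = 100) {
  age <- 0:(max_age - 1)
  qx <- ifelse(age == 0, 0.004,
        ifelse(age <= 4, 3e-4,
               pmin(2e-4 * exp(0.085 * (age - 5)), 0.7)))
  tibble::tibble(age = age, qx = qx)
}

.qx_at <- function(life_table, age) {
  i <- match(age, life_table$age)
  if (anyNA(i))
    stop("life table does not cover age(s) ",
         paste(age[is.na(i)], collapse = ", "), call. = FALSE)
  life_table$qx[i]
}

#' Evaluate one arm of the decision tree
#'
#' Cohort evaluation of the two-arm decision tree. Stage 1 covers the first
#' `horizon_years` of life in annual cycles: each year, children with no
#' rickets history contract rickets with the (odds-ratio-adjusted) annual
#' risk; onset charges the subgroup treatment cost and replaces the baseline
#' utility with the rickets utility for `rickets_duration` years (pro-rated
#' in the final part-year, truncated at the horizon in the base case);
#' all-cause mortality from the life table applies at the end of each cycle.
#' With `horizon = "lifetime"` stage 2 appends annual cycles to `max_age`
#' via [lifetime_extension()].
#'
#' Expected QALYs are the discounted sum over cycles of
#' path-probability-weighted utilities; expected cost is the discounted
#' treatment cost at onset plus `intervention_cost` (a present value computed
#' by [intervention_cost_per_child()]) for the intervention arm.
#'
#' @param annual_risk Subgroup annual rickets risk (probability).
#' @param treatment_cost Subgroup mean rickets management cost (£).
#' @param or_effect Odds ratio applied to the annual risk (1 for the
#'   comparator arm, 0.41 for the intervention arm).
#' @param intervention_cost Present-value intervention cost per child (£);
#'   0 for the comparator arm.
#' @param health A [health_params()] bundle.
#' @param config A [cea_config()] bundle.
#' @param life_table Data frame with columns `age`, `qx`; default
#'   [synthetic_life_table()].
#' @param horizon `"base"` (stage 1 only) or `"lifetime"`.
#' @param trace Keep the per-cycle audit trace (default `TRUE`; the
#'   uncertainty analyses disable it for speed).
#' @return An object of class `strategy_outcome`: list with `expected_cost`,
#'   `expected_qalys`, a per-cycle audit `trace` tibble, and the stage-1
#'   exit composition (`p_alive`, `p_rickets_alive`).
#' @export
evaluate_arm <- function(annual_risk, treatment_cost, or_effect = 1,
                         intervention_cost = 0,
                         health = health_params(), config = cea_config(),
                         life_table = synthetic_life_table(config$max_age),
                         horizon = c("base", "lifetime"), trace = TRUE) {
  horizon <- match.arg(horizon)
  stopifnot(annual_risk >= 0, annual_risk <= 1, treatment_cost >= 0)
  p <- apply_or(annual_risk, or_effect)
  r <- config$discount_rate
  offset <- c(start = 0, mid = 0.5, end = 1)[[config$timing]]
  ny <- config$horizon_years

  p_never <- 1
  p_onset <- numeric(ny)      # alive mass with onset at year o (1-based)
  p_dead <- 0
  qalys <- 0; cost <- intervention_cost
  tr_alive <- tr_onset <- tr_util <- tr_cost <- tr_disc <- numeric(ny)

  for (t in seq_len(ny) - 1) {
    disc <- (1 + r)^-(t + offset)
    # onset draw at the start of the cycle, among the rickets-free alive
    new_onset <- p_never * p
    p_never <- p_never - new_onset
    p_onset[t + 1] <- p_onset[t + 1] + new_onset
    cost_t <- new_onset * treatment_cost
    # utility accrual for the cycle
    u_base <- .baseline_mixed(t, config)
    frac <- pmin(pmax(health$rickets_duration - (t - (seq_len(ny) - 1)), 0), 1)
    u_onset <- frac * health$rickets_utility + (1 - frac) * u_base
    util_t <- p_never * u_base + sum(p_onset * u_onset)
    qalys <- qalys + disc * util_t
    cost <- cost + disc * cost_t
    # end-of-cycle mortality
    qx <- .qx_at(life_table, t)
    died <- (p_never + sum(p_onset)) * qx
    p_never <- p_never * (1 - qx)
    p_onset <- p_onset * (1 - qx)
    p_dead <- p_dead + died
    tr_alive[t + 1] <- p_never + sum(p_onset)
    tr_onset[t + 1] <- new_onset
    tr_util[t + 1] <- util_t
    tr_cost[t + 1] <- cost_t
    tr_disc[t + 1] <- disc
  }

  out <- structure(
    list(expected_cost = cost, expected_qalys = qalys,
         trace = if (trace)
           tibble::tibble(stage = 1L, cycle = seq_len(ny) - 1L,
                          age = seq_len(ny) - 1L, p_alive = tr_alive,
                          p_onset = tr_onset, utility = tr_util,
                          cost = tr_cost, disc = tr_disc),
         p_alive = p_never + sum(p_onset),
         p_rickets_alive = sum(p_onset),
         health = health, config = config),
    class = "strategy_outcome")
  if (horizon == "lifetime")
    out <- lifetime_extension(out, health = health, config = config,
                              life_table = life_table, trace = trace)
  out
}

#' Extend a stage-1 outcome over the lifetime horizon
#'
#' Appends annual cycles from the end of stage 1 to `max_age`. At entry the
#' surviving cohort splits into four independent sub-cohorts: lifelong
#' complications (probability `complication_probability` among surviving
#' rickets cases) crossed with vitamin D deficiency (population prevalence,
#' identical in both arms). Complication sufferers accrue the complication
#' disutility and annual management cost for life; deficient individuals
#' accrue the deficiency disutility from `deficiency_onset_age` and face
#' mortality multiplied by `mortality_rr` from `mortality_onset_age`.
#' Everything is discounted on the same clock as stage 1.
#'
#' @param stage1 A `strategy_outcome` produced by [evaluate_arm()] with
#'   `horizon = "base"`.
#' @param health,config,life_table As in [evaluate_arm()]; the life table
#'   must cover every age up to `config$max_age - 1`.
#' @return A `strategy_outcome` over the lifetime horizon.
#' @export
lifetime_extension <- function(stage1, health = stage1$health,
                               config = stage1$config,
                               life_table = synthetic_life_table(config$max_age),
                               trace = !is.null(stage1$trace)) {
  stopifnot(inherits(stage1, "strategy_outcome"))
  r <- config$discount_rate
  offset <- c(start = 0, mid = 0.5, end = 1)[[config$timing]]
  ages <- config$horizon_years:(config$max_age - 1)

  p_comp <- health$complication_probability * stage1$p_rickets_alive
  p_nocomp <- stage1$p_alive - p_comp
  d <- health$deficiency_prevalence
  # sub-cohort masses: complication status x deficiency status
  mass <- c(cd = p_comp * d, c0 = p_comp * (1 - d),
            nd = p_nocomp * d, n0 = p_nocomp * (1 - d))
  comp_flag <- c(cd = 1, c0 = 1, nd = 0, n0 = 0)
  def_flag <- c(cd = 1, c0 = 0, nd = 1, n0 = 0)

  n <- length(ages)
  disc <- (1 + r)^-(ages + offset)
  u_base <- .baseline_mixed(ages, config)
  qx <- .qx_at(life_table, ages)
  util_t <- cost_t <- alive_end <- numeric(n)
  final_mass <- numeric(4)
  for (j in seq_along(mass)) {    # 4 sub-cohorts, each fully vectorised
    dec <- comp_flag[j] * health$complication_disutility +
      def_flag[j] * health$deficiency_disutility *
        (ages >= health$deficiency_onset_age)
    u <- pmin(pmax(u_base - dec, 0), 1)
    qx_eff <- pmin(qx * ifelse(def_flag[j] == 1 &
                                 ages >= health$mortality_onset_age,
                               health$mortality_rr, 1), 1)
    surv <- cumprod(1 - qx_eff)
    alive_start <- mass[j] * c(1, surv[-n])
    util_t <- util_t + alive_start * u
    cost_t <- cost_t + alive_start *
      (comp_flag[j] * health$complication_annual_cost +
       def_flag[j] * health$deficiency_annual_cost)
    alive_end <- alive_end + mass[j] * surv
    final_mass[j] <- mass[j] * surv[n]
  }
  qalys <- stage1$expected_qalys + sum(disc * util_t)
  cost <- stage1$expected_cost + sum(disc * cost_t)

  structure(
    list(expected_cost = cost, expected_qalys = qalys,
         trace = if (trace) dplyr::bind_rows(
           stage1$trace,
           tibble::tibble(stage = 2L, cycle = as.integer(ages),
                          age = as.integer(ages), p_alive = alive_end,
                          p_onset = 0, utility = util_t, cost = cost_t,
                          disc = disc)),
         p_alive = sum(final_mass), p_rickets_alive = stage1$p_rickets_alive,
         health = health, config = config),
    class = "strategy_outcome")
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("<strategy_outcome> expected cost £%.4f, expected QALYs %.6f\n",
              x$expected_cost, x$expected_qalys))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname evaluate_arm
#' @param x A `strategy_outcome`.
#' @param ... Unused.
#' @export
tidy.strategy_outcome <- function(x, ...) x$trace

#' @rdname evaluate_arm
#' @export
glance.strategy_outcome <- function(x, ...) {
  tibble::tibble(expected_cost = x$expected_cost,
                 expected_qalys = x$expected_qalys,
                 p_alive = x$p_alive,
                 p_rickets_alive = x$p_rickets_alive,
                 cycles = if (is.null(x$trace)) NA_integer_ else nrow(x$trace))
}
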