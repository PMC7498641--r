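#' Default skin-tone subgroup table
#'
#' Observational-dataset summaries per skin-tone stratum: registry case
#' counts over the 6-year observation window, census denominators (children
#' under 4), and mean/SD rickets management costs at 2016-17 prices.
#'
#' @return Tibble with columns `subgroup`, `cases_total`, `window_years`,
#'   `population_at_risk`, `cost_mean`, `cost_sd_observed`.
#' @export
subgroup_defaults <- function() {
  tibble::tibble(
    subgroup = c("light", "medium", "dark"),
    cases_total = c(2, 29, 25),
    window_years = 6,
    population_at_risk = c(17344, 14117, 4952),
    cost_mean = c(1750, 2385, 7305),
    cost_sd_observed = c(48, 3759, 16208))
}

#' Cost-side configuration
#'
#' Supplement prices and programme costing policy. Defaults are the Healthy
#' Start pack prices (woman £0.74, child £1.52, 56-day packs), a 270-day
#' supplemented pregnancy (which reproduces the published £3.57 per
#' pregnancy), a £10,000/year administration budget spread over the 36,413
#' children under 4 in the region, and the `"incremental"` payer-coverage
#' policy (the NHS pays only for the uptake increase the programme induces).
#'
#' @param woman_pack_price,child_pack_price £ per pack.
#' @param woman_days_per_pack,child_days_per_pack Days one pack covers.
#' @param pregnancy_days Supplemented days per pregnancy (default 270).
#' @param child_days_per_year Supplemented days per child-year (default 365).
#' @param target_population Children the administration budget is spread
#'   over (default 36,413, the full regional under-4 census).
#' @param coverage Payer-coverage policy, see
#'   [intervention_cost_per_child()].
#' @param price_year Label for the price year.
#' @return A list of class `cost_config`.
#' @export
cost_config <- function(woman_pack_price = 0.74, woman_days_per_pack = 56,
                        child_pack_price = 1.52, child_days_per_pack = 56,
                        pregnancy_days = 270, child_days_per_year = 365,
                        target_population = 36413,
                        coverage = "incremental",
                        price_year = "2016-17") {
  if (any(c(woman_pack_price, child_pack_price) < 0))
    stop("cost_config: pack prices must be non-negative", call. = FALSE)
  if (any(c(woman_days_per_pack, child_days_per_pack, pregnancy_days,
            child_days_per_year) <= 0) || target_population <= 0)
    stop("cost_config: durations and target_population must be positive",
         call. = FALSE)
  structure(list(woman_pack_price = woman_pack_price,
                 woman_days_per_pack = woman_days_per_pack,
                 child_pack_price = child_pack_price,
                 child_days_per_pack = child_days_per_pack,
                 pregnancy_days = pregnancy_days,
                 child_days_per_year = child_days_per_year,
                 target_population = target_population,
                 coverage = coverage, price_year = price_year),
            class = "cost_config")
}

# health_params built from a named list of registry parameter values
.health_from_values <- function(values, complication_annual_cost = 500,
                                deficiency_prevalence = 0.23,
                                deficiency_annual_cost = 0) {
  health_params(
    rickets_utility = min(max(values$rickets_utility, 0), 1),
    rickets_duration = max(values$rickets_duration, 0),
    complication_probability = min(max(values$complication_probability, 0), 1),
    complication_disutility = min(max(values$complication_disutility, 0), 1),
    complication_annual_cost = complication_annual_cost,
    deficiency_prevalence = deficiency_prevalence,
    deficiency_disutility = min(max(values$deficiency_disutility, 0), 1),
    deficiency_onset_age = max(values$deficiency_onset_age, 0),
    deficiency_annual_cost = deficiency_annual_cost,
    mortality_rr = max(values$mortality_rr, .Machine$double.eps),
    mortality_onset_age = max(values$mortality_onset_age, 0))
}

#' Evaluate the full model for one subgroup at given parameter values
#'
#' The workhorse behind the deterministic base case, the PSA, univariate
#' sweeps and threshold search: takes a complete named list of parameter
#' values (a row of [registry_sample()] or [registry_points()], possibly
#' with overrides), builds both arms, and returns the incremental
#' comparison.
#'
#' @param values Named list/one-row data frame of parameter values covering
#'   every required registry parameter.
#' @param subgroup `"light"`, `"medium"` or `"dark"`.
#' @param config A [cea_config()].
#' @param costcfg A [cost_config()].
#' @param life_table Life table data frame (`age`, `qx`).
#' @param horizon `"base"` or `"lifetime"`.
#' @param ... Passed to the health-parameter builder
#'   (`complication_annual_cost`, `deficiency_prevalence`,
#'   `deficiency_annual_cost`).
#' @return A `cea_result` row with `subgroup` and `horizon` columns added.
#' @export
evaluate_cea <- function(values, subgroup, config = cea_config(),
                         costcfg = cost_config(),
                         life_table = synthetic_life_table(config$max_age),
                         horizon = c("base", "lifetime"), ...) {
  horizon <- match.arg(horizon)
  values <- as.list(values)
  risk <- min(max(values[[paste0("risk_", subgroup)]], 0), 1)
  tcost <- max(values[[paste0("cost_", subgroup)]], 0)
  health <- .health_from_values(values, ...)

  child_annual <- supplement_cost(costcfg$child_pack_price,
                                  costcfg$child_days_per_pack,
                                  costcfg$child_days_per_year)
  pregnancy <- supplement_cost(costcfg$woman_pack_price,
                               costcfg$woman_days_per_pack,
                               costcfg$pregnancy_days)
  icost <- intervention_cost_per_child(
    child_annual_cost = child_annual, pregnancy_cost = pregnancy,
    uptake_increase_child = min(max(values$uptake_increase_child, 0), 1),
    uptake_increase_woman = min(max(values$uptake_increase_woman, 0), 1),
    uptake_baseline_child = min(max(values$uptake_baseline_child, 0), 1),
    uptake_baseline_woman = min(max(values$uptake_baseline_woman, 0), 1),
    admin_budget_per_year = max(values$admin_budget, 0),
    target_population = costcfg$target_population,
    horizon_years = config$horizon_years,
    discount_rate = config$discount_rate,
    coverage = costcfg$coverage, timing = config$timing)

  comp <- evaluate_arm(risk, tcost, or_effect = 1, intervention_cost = 0,
                       health = health, config = config,
                       life_table = life_table, horizon = horizon,
                       trace = FALSE)
  intv <- evaluate_arm(risk, tcost, or_effect = max(values$or_rickets,
                                                    .Machine$double.eps),
                       intervention_cost = icost,
                       health = health, config = config,
                       life_table = life_table, horizon = horizon,
                       trace = FALSE)
  out <- cea_compare(comp, intv)
  out$subgroup <- subgroup
  out$horizon <- horizon
  out[, c("subgroup", "horizon",
          setdiff(names(out), c("subgroup", "horizon")))]
}

#' Deterministic base-case (or lifetime-scenario) analysis
#'
#' Evaluates every subgroup at the registry point estimates and returns the
#' incremental table: the deterministic analogue of the published base-case
#' results (intervention dominant for dark skin tone, ICER near the £20,000
#' threshold for medium, far above it for light).
#'
#' @param registry Parameter registry tibble; default [default_parameters()].
#' @param subgroups Character vector of subgroup labels.
#' @inheritParams evaluate_cea
#' @return Tibble with one `cea_result` row per subgroup.
#' @examples
#' cea_basecase()
#' @export
cea_basecase <- function(registry = default_parameters(),
                         subgroups = c("light", "medium", "dark"),
                         config = cea_config(), costcfg = cost_config(),
                         life_table = synthetic_life_table(config$max_age),
                         horizon = "base", ...) {
  registry_validate(registry)
  pts <- registry_points(registry)
  purrr::map_dfr(subgroups, function(sg)
    evaluate_cea(pts, sg, config = config, costcfg = costcfg,
                 life_table = life_table, horizon = horizon, ...))
}

#' Lifetime-scenario vs base-case ICER comparison
#'
#' Runs the deterministic analysis on both horizons and tabulates the ICERs
#' side by side. With a positive complication probability the scenario
#' ICERs fall below the base-case ICERs: the intervention prevents lifelong
#' complications whose disutility and costs the base case ignores.
#'
#' @inheritParams cea_basecase
#' @return Tibble with columns `subgroup`, `icer_base`, `status_base`,
#'   `icer_scenario`, `status_scenario`.
#' @export
cea_scenario <- function(registry = default_parameters(),
                         subgroups = c("light", "medium", "dark"),
                         config = cea_config(), costcfg = cost_config(),
                         life_table = synthetic_life_table(config$max_age),
                         ...) {
  base <- cea_basecase(registry, subgroups, config, costcfg, life_table,
                       horizon = "base", ...)
  life <- cea_basecase(registry, subgroups, config, costcfg, life_table,
                       horizon = "lifetime", ...)
  tibble::tibble(
    subgroup = base$subgroup,
    icer_base = base$icer, status_base = base$status,
    icer_scenario = life$icer, status_scenario = life$status)
}
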