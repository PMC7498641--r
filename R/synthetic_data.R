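#' Configuration for the synthetic observational dataset
#'
#' The generator emulates the structure of the Manchester observational
#' dataset the analysis assumes: around 57 rickets cases over a 6-year
#' window split roughly 2/29/25 across light/medium/dark skin tones, ~95%
#' of onsets before 48 months with mean onset age ~21.16 months, 63.16%
#' male, subgroup treatment-cost means/SDs of £1,750(48) / £2,385(3,759) /
#' £7,305(16,208), and census denominators 17,344 / 14,117 / 4,952.
#'
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param window_years Observation window (years).
#' @param populations Named census counts of children under 4 per subgroup.
#' @param annual_rates_per_100k Named annual incidence per 100,000.
#' @param onset_before_48mo_prob Probability of onset before 48 months.
#' @param onset_mean_months Mean onset age (months).
#' @param cost_means,cost_sds Named treatment-cost moments (£) per subgroup.
#' @param sex_male_prob Probability a case is male.
#' @param count_model `"poisson"` (default; appropriate for tiny per-child
#'   risks) or `"binomial"` case counts.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, window_years = 6,
                         populations = c(light = 17344, medium = 14117,
                                         dark = 4952),
                         annual_rates_per_100k = c(light = 1.92,
                                                   medium = 34.23,
                                                   dark = 84.14),
                         onset_before_48mo_prob = 0.95,
                         onset_mean_months = 21.16,
                         cost_means = c(light = 1750, medium = 2385,
                                        dark = 7305),
                         cost_sds = c(light = 48, medium = 3759,
                                      dark = 16208),
                         sex_male_prob = 0.6316,
                         count_model = c("poisson", "binomial")) {
  stopifnot(window_years > 0, all(populations > 0),
            all(annual_rates_per_100k >= 0),
            onset_before_48mo_prob >= 0, onset_before_48mo_prob <= 1,
            onset_mean_months > 0, all(cost_means > 0), all(cost_sds >= 0),
            sex_male_prob >= 0, sex_male_prob <= 1)
  groups <- names(populations)
  stopifnot(identical(sort(groups), sort(names(annual_rates_per_100k))),
            identical(sort(groups), sort(names(cost_means))),
            identical(sort(groups), sort(names(cost_sds))))
  structure(list(seed = as.integer(seed), window_years = window_years,
                 populations = populations,
                 annual_rates_per_100k = annual_rates_per_100k,
                 onset_before_48mo_prob = onset_before_48mo_prob,
                 onset_mean_months = onset_mean_months,
                 cost_means = cost_means, cost_sds = cost_sds,
                 sex_male_prob = sex_male_prob,
                 count_model = match.arg(count_model)),
            class = "synth_config")
}

#' Bundled NHS-tariff-style price list (synthetic)
#'
#' Six stylised tariff lines used to decompose synthetic case costs into
#' line items. The codes and prices are synthetic stand-ins for the NHS
#' 2016-17 tariff database, which is not redistributed.
#'
#' @return Tibble with columns `code`, `description`, `ref_price`.
#' @export
tariff_fixture <- function() {
  tibble::tibble(
    code = c("OPD-PAED", "XR-LIMB", "BIO-PANEL", "IP-ADMIT", "RX-VITD",
             "PHYSIO"),
    description = c("Paediatric outpatient attendance",
                    "Limb radiograph", "Bone biochemistry panel",
                    "Inpatient admission episode",
                    "Vitamin D therapy course", "Physiotherapy session"),
    ref_price = c(163, 31, 12, 1489, 18, 47))
}

# gamma shape such that a gamma with the given mean has P(X < cut) = prob.
# P(X < cut) is U-shaped in the shape k (tends to 1 as k -> 0 and, when
# mean < cut, as k -> Inf); calibrate on the increasing branch k >= argmin,
# where larger shape means lighter tail beyond the cut.
.calibrate_onset_shape <- function(mean, cut = 48, prob = 0.95) {
  prob <- min(max(prob, 1e-6), 0.995)
  pcut <- function(k) stats::pgamma(cut, shape = k, scale = mean / k)
  opt <- stats::optimize(pcut, interval = c(1e-3, 50))
  if (prob < opt$objective)
    stop(sprintf(
      "onset calibration infeasible: P(<%g) cannot go below %.3f at mean %g",
      cut, opt$objective, mean), call. = FALSE)
  stats::uniroot(function(logk) pcut(exp(logk)) - prob,
                 lower = log(opt$minimum), upper = log(1e6),
                 tol = 1e-12)$root |> exp()
}

# onset ages: gamma calibrated to (mean, P(<48) = prob), sampled by mixing
# the below-48 and above-48 conditionals so the below-48 share is exact
.sample_onset_ages <- function(n, cfg) {
  if (n == 0) return(numeric(0))
  k <- .calibrate_onset_shape(cfg$onset_mean_months, 48,
                              cfg$onset_before_48mo_prob)
  scale <- cfg$onset_mean_months / k
  p48 <- stats::pgamma(48, shape = k, scale = scale)
  below <- stats::runif(n) < cfg$onset_before_48mo_prob
  u <- stats::runif(n)
  q <- ifelse(below, u * p48, p48 + u * (1 - p48))
  stats::qgamma(q, shape = k, scale = scale)
}

# split a case total into tariff line items; quantities 1, prices summing
# exactly to the total (Dirichlet-weighted, cosmetic for I/O testing)
.decompose_line_items <- function(case_id, total, tariff) {
  n_items <- sample(3:nrow(tariff), 1)
  rows <- sample(nrow(tariff), n_items)
  w <- stats::rgamma(n_items, shape = 1)
  w <- w / sum(w)
  price <- round(total * w, 2)
  price[n_items] <- round(total - sum(price[-n_items]), 2)
  tibble::tibble(case_id = case_id, code = tariff$code[rows],
                 description = tariff$description[rows],
                 unit_price = price, quantity = 1)
}

#' Generate a synthetic observational dataset
#'
#' Per subgroup, the case count is Poisson with mean
#' `rate x population x window` (binomial per child-year available via the
#' config); onset ages follow a right-skewed gamma calibrated so the
#' configured share of onsets falls before 48 months at the configured mean;
#' per-case treatment costs are gamma draws with the subgroup's mean and SD,
#' decomposed into tariff line items that sum exactly to the case total.
#'
#' @param cfg A [synth_config()].
#' @return List of class `synth_dataset` with tibbles `cases` (`case_id`,
#'   `subgroup`, `sex`, `onset_age_months`, `treatment_cost_total`),
#'   `line_items` (`case_id`, `code`, `description`, `unit_price`,
#'   `quantity`) and `census` (`subgroup`, `population_at_risk`), plus the
#'   generating `config`.
#' @export
generate_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(cfg$seed)
  tariff <- tariff_fixture()
  groups <- names(cfg$populations)
  cases <- list(); items <- list(); next_id <- 1L
  for (g in groups) {
    lambda <- cfg$annual_rates_per_100k[[g]] / 1e5 * cfg$populations[[g]] *
      cfg$window_years
    n <- if (cfg$count_model == "poisson") {
      stats::rpois(1, lambda)
    } else {
      annual <- cfg$annual_rates_per_100k[[g]] / 1e5
      stats::rbinom(1, round(cfg$populations[[g]] * cfg$window_years), annual)
    }
    if (n == 0) next
    mean_g <- cfg$cost_means[[g]]; sd_g <- cfg$cost_sds[[g]]
    costs <- if (sd_g == 0) rep(mean_g, n) else
      dist_sample(fit_from_moments(mean_g, sd_g, "gamma"), n)
    ids <- sprintf("case_%04d", next_id:(next_id + n - 1L))
    next_id <- next_id + n
    cases[[g]] <- tibble::tibble(
      case_id = ids, subgroup = g,
      sex = ifelse(stats::runif(n) < cfg$sex_male_prob, "male", "female"),
      onset_age_months = .sample_onset_ages(n, cfg),
      treatment_cost_total = round(costs, 2))
    items[[g]] <- purrr::map_dfr(seq_len(n), function(i)
      .decompose_line_items(ids[i], round(costs[i], 2), tariff))
  }
  empty_cases <- tibble::tibble(case_id = character(), subgroup = character(),
                                sex = character(),
                                onset_age_months = numeric(),
                                treatment_cost_total = numeric())
  empty_items <- tibble::tibble(case_id = character(), code = character(),
                                description = character(),
                                unit_price = numeric(), quantity = numeric())
  structure(
    list(cases = dplyr::bind_rows(c(list(empty_cases), cases)),
         line_items = dplyr::bind_rows(c(list(empty_items), items)),
         census = tibble::tibble(subgroup = groups,
                                 population_at_risk = unname(cfg$populations)),
         config = cfg),
    class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("<synth_dataset> %d cases over %gy (seed %d)\n",
              nrow(x$cases), x$config$window_years, x$config$seed))
  print(dplyr::count(x$cases, .data$subgroup))
  invisible(x)
}

#' Subgroup summaries of a (synthetic or real) observational dataset
#'
#' Counts cases, estimates annual risks via [incidence_rates()], and
#' computes mean/SD treatment costs per subgroup.
#'
#' @param dataset A `synth_dataset`, or a list with tibbles `cases` and
#'   `census` in the same schema.
#' @param window_years Observation window; defaults to the generating
#'   config's window when present.
#' @return Tibble with columns `subgroup`, `cases_total`, `window_years`,
#'   `population_at_risk`, `annual_risk`, `per_100k`, `cumulative_4yr`,
#'   `cost_mean`, `cost_sd`.
#' @export
summarise_dataset <- function(dataset,
                              window_years = dataset$config$window_years) {
  counts <- dataset$census |>
    dplyr::left_join(
      dplyr::count(dataset$cases, .data$subgroup, name = "cases_total"),
      by = "subgroup") |>
    dplyr::mutate(cases_total = dplyr::coalesce(.data$cases_total, 0L),
                  window_years = window_years)
  rates <- incidence_rates(counts)
  costs <- dataset$cases |>
    dplyr::group_by(.data$subgroup) |>
    dplyr::summarise(cost_mean = mean(.data$treatment_cost_total),
                     cost_sd = stats::sd(.data$treatment_cost_total),
                     .groups = "drop")
  dplyr::left_join(rates, costs, by = "subgroup")
}

#' End-to-end generator/estimator round trip
#'
#' Generates a dataset, runs the epidemiology and costing estimators on it,
#' and reports recovery of the configured inputs: whether the configured
#' expected case count lies in the exact 95% Poisson interval implied by
#' the observed count, and whether the observed mean cost lies within 2
#' standard errors (configured SD / sqrt(n)) of the configured mean.
#'
#' @param cfg A [synth_config()].
#' @return Tibble, one row per subgroup: `subgroup`, `expected_cases`,
#'   `observed_cases`, `rate_recovered`, `cost_mean_config`,
#'   `cost_mean_observed`, `cost_recovered` (NA when the seed produced no
#'   cases).
#' @export
roundtrip_check <- function(cfg = synth_config()) {
  ds <- generate_dataset(cfg)
  s <- summarise_dataset(ds)
  purrr::map_dfr(names(cfg$populations), function(g) {
    row <- s[s$subgroup == g, ]
    k <- row$cases_total
    lambda <- cfg$annual_rates_per_100k[[g]] / 1e5 * cfg$populations[[g]] *
      cfg$window_years
    # exact Poisson 95% CI for the mean given the observed count
    ci_lo <- if (k == 0) 0 else stats::qchisq(0.025, 2 * k) / 2
    ci_hi <- stats::qchisq(0.975, 2 * (k + 1)) / 2
    n_obs <- max(k, 1)
    se <- cfg$cost_sds[[g]] / sqrt(n_obs)
    tibble::tibble(
      subgroup = g, expected_cases = lambda, observed_cases = k,
      rate_recovered = lambda >= ci_lo && lambda <= ci_hi,
      cost_mean_config = cfg$cost_means[[g]],
      cost_mean_observed = row$cost_mean,
      cost_recovered = if (k == 0) NA else
        abs(row$cost_mean - cfg$cost_means[[g]]) <= 2 * se)
  })
}

#' Write a synthetic dataset as CSV files
#'
#' Emits the same schemas the epidemiology and costing readers consume:
#' `cases.csv`, `line_items.csv`, `census.csv`.
#'
#' @param dataset A `synth_dataset`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_dataset_csv <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(cases = file.path(dir, "cases.csv"),
             line_items = file.path(dir, "line_items.csv"),
             census = file.path(dir, "census.csv"))
  utils::write.csv(dataset$cases, files["cases"], row.names = FALSE)
  utils::write.csv(dataset$line_items, files["line_items"], row.names = FALSE)
  utils::write.csv(dataset$census, files["census"], row.names = FALSE)
  invisible(unname(files))
}
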