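test_that("annual rates reproduce the registry-derived incidence table", {
  rates <- incidence_rates(subgroup_defaults())
  expect_equal(round(rates$per_100k[rates$subgroup == "light"], 2), 1.92)
  expect_equal(round(rates$per_100k[rates$subgroup == "dark"], 2), 84.14)
  expect_equal(rates$per_100k[rates$subgroup == "medium"], 34.23,
               tolerance = 0.01 / 34.23)
  general <- incidence_rates(data.frame(
    subgroup = "general", cases_total = 56, window_years = 6,
    population_at_risk = 36413))
  expect_equal(round(general$per_100k, 2), 25.63)
})

test_that("zero cases give zero risk and cumulative risk obeys the
           Bernoulli inequality", {
  z <- incidence_rates(data.frame(subgroup = "x", cases_total = 0,
                                  window_years = 6,
                                  population_at_risk = 1000))
  expect_equal(z$annual_risk, 0)
  expect_equal(z$cumulative_4yr, 0)

  p <- seq(0, 1, by = 0.05)
  df <- data.frame(subgroup = "x", cases_total = p * 1000, window_years = 1,
                   population_at_risk = 1000)
  comp <- incidence_rates(df)
  lin <- incidence_rates(df, cumulative = "linear")
  expect_true(all(comp$cumulative_4yr <= lin$cumulative_4yr + 1e-12))
  expect_true(all(comp$cumulative_4yr >= comp$annual_risk - 1e-12))
  expect_equal(comp$per_100k, comp$annual_risk * 1e5)
})

test_that("annual rate scales linearly in cases and inversely in population", {
  base <- incidence_rates(data.frame(subgroup = "x", cases_total = 10,
                                     window_years = 5,
                                     population_at_risk = 2000))
  dbl <- incidence_rates(data.frame(subgroup = "x", cases_total = 20,
                                    window_years = 5,
                                    population_at_risk = 2000))
  half <- incidence_rates(data.frame(subgroup = "x", cases_total = 10,
                                     window_years = 5,
                                     population_at_risk = 4000))
  expect_equal(dbl$annual_risk, 2 * base$annual_risk)
  expect_equal(half$annual_risk, base$annual_risk / 2)
})

test_that("pooled medium+dark rate lies between the subgroup rates", {
  sg <- subgroup_defaults()
  md <- sg[sg$subgroup %in% c("medium", "dark"), ]
  pooled <- incidence_rates(data.frame(
    subgroup = "medium+dark", cases_total = sum(md$cases_total),
    window_years = 6, population_at_risk = sum(md$population_at_risk)))
  rates <- incidence_rates(md)
  expect_gt(pooled$annual_risk, min(rates$annual_risk))
  expect_lt(pooled$annual_risk, max(rates$annual_risk))
})

test_that("Wilson interval matches prop.test and the printed onset CI", {
  ci <- onset_proportion_ci(54, 57, 0.95)
  expect_equal(round(ci$lower, 2), 0.86)
  expect_equal(round(ci$upper, 2), 0.98)

  # independent oracle: score interval from stats::prop.test (no correction)
  for (case in list(c(54, 57), c(1, 10), c(5, 10), c(99, 100), c(30, 200))) {
    k <- case[1]; n <- case[2]
    ours <- onset_proportion_ci(k, n, 0.95)
    ref <- prop.test(k, n, correct = FALSE)$conf.int
    expect_equal(ours$lower, ref[1], tolerance = 1e-9)
    expect_equal(ours$upper, ref[2], tolerance = 1e-9)
    expect_lte(ours$lower, k / n)
    expect_gte(ours$upper, k / n)
  }

  expect_equal(onset_proportion_ci(0, 10)$lower, 0, tolerance = 1e-9)
  expect_error(onset_proportion_ci(5, 10, level = 1.2), "level")
  cp <- onset_proportion_ci(54, 57, method = "clopper-pearson")
  expect_lt(cp$lower, onset_proportion_ci(54, 57)$lower)  # CP is wider
})

test_that("apply_or follows the odds-scale identity and its limits", {
  expect_equal(apply_or(0.3, 1), 0.3)
  expect_equal(round(apply_or(0.5, 0.41), 4), 0.2908)
  # rare-outcome limit: OR ~ RR
  expect_equal(apply_or(1e-4, 0.41), 0.41e-4, tolerance = 1e-4)
  # inverse recovers the input
  for (p in c(0.001, 0.2, 0.7)) {
    expect_equal(apply_or(apply_or(p, 0.41), 1 / 0.41), p, tolerance = 1e-12)
  }
  # monotone in both arguments
  ps <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(apply_or(ps, 0.41)) > 0))
  expect_true(all(diff(sapply(c(0.2, 0.5, 1, 2), function(o)
    apply_or(0.3, o))) > 0))
  expect_error(apply_or(1, 0.41), "undefined")
  expect_error(apply_or(0.5, -1))
})
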