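test_that("supplement costs pro-rate pack prices over the period", {
  expect_equal(round(supplement_cost(0.74, 56, 270), 2), 3.57)
  expect_equal(supplement_cost(0.74, 56, 0), 0)
  expect_equal(supplement_cost(1.52, 56, 365), 9.907, tolerance = 5e-4)
  expect_error(supplement_cost(-1, 56, 10))
  expect_error(supplement_cost(1, 0, 10))
})

test_that("treatment cost sums tariff line items, per case when asked", {
  expect_equal(rickets_treatment_cost(
    data.frame(unit_price = numeric(0), quantity = numeric(0)))$total_cost, 0)

  set.seed(9)
  items <- data.frame(unit_price = round(runif(17, 1, 500), 2),
                      quantity = sample(1:4, 17, replace = TRUE))
  brute <- 0
  for (i in seq_len(nrow(items)))
    brute <- brute + items$unit_price[i] * items$quantity[i]
  expect_equal(rickets_treatment_cost(items)$total_cost, brute)

  items$case_id <- rep(c("a", "b"), length.out = 17)
  per_case <- rickets_treatment_cost(items)
  expect_equal(sum(per_case$total_cost), brute)
  expect_equal(nrow(per_case), 2)
})

test_that("present value matches the annuity closed form and rate
           monotonicity", {
  expect_equal(discount(c(3, 4, 5), 0), 12)
  r <- 0.035; T <- 25; c0 <- 7.3
  ann <- c0 * (1 - (1 + r)^-T) / (1 - (1 + r)^-1)
  expect_equal(discount(rep(c0, T), r, "start"), ann, tolerance = 1e-12)
  expect_equal(discount(10, 0.99, "start"), 10)
  expect_equal(discount(10, 0.05, "end"), 10 / 1.05)
  expect_equal(discount(10, 0.05, "mid"), 10 / 1.05^0.5)
  rates <- seq(0, 0.2, by = 0.02)
  pv <- sapply(rates, function(x) discount(rep(1, 10), x))
  expect_true(all(diff(pv) < 0))
})

test_that("intervention cost per child reproduces the hand-computed total", {
  # 39.60 x 0.20 + 3.57 x 0.17 + 40,000 / 36,413, undiscounted
  got <- intervention_cost_per_child(
    child_annual_cost = 9.90, pregnancy_cost = 3.57,
    uptake_increase_child = 0.20, uptake_increase_woman = 0.17,
    admin_budget_per_year = 10000, target_population = 36413,
    horizon_years = 4, discount_rate = 0)
  expect_equal(got, 39.60 * 0.20 + 3.57 * 0.17 + 40000 / 36413,
               tolerance = 1e-12)
  expect_equal(round(got, 2), 9.63)

  expect_equal(intervention_cost_per_child(9.90, 3.57, 0, 0,
                                           admin_budget_per_year = 0), 0)

  # linearity in the admin budget
  base <- intervention_cost_per_child(9.90, 3.57, 0.2, 0.17,
                                      admin_budget_per_year = 10000,
                                      discount_rate = 0)
  dbl <- intervention_cost_per_child(9.90, 3.57, 0.2, 0.17,
                                     admin_budget_per_year = 20000,
                                     discount_rate = 0)
  expect_equal(dbl - base, 40000 / 36413, tolerance = 1e-12)
})

test_that("cost operations are homogeneous of degree 1 in prices", {
  k <- 2.5
  expect_equal(supplement_cost(k * 0.74, 56, 270),
               k * supplement_cost(0.74, 56, 270))
  items <- data.frame(unit_price = c(10, 20), quantity = c(1, 3))
  scaled <- items; scaled$unit_price <- k * scaled$unit_price
  expect_equal(rickets_treatment_cost(scaled)$total_cost,
               k * rickets_treatment_cost(items)$total_cost)
  expect_equal(
    intervention_cost_per_child(k * 9.9, k * 3.57, 0.2, 0.17,
                                admin_budget_per_year = k * 1e4),
    k * intervention_cost_per_child(9.9, 3.57, 0.2, 0.17,
                                    admin_budget_per_year = 1e4),
    tolerance = 1e-12)
})

test_that("payer-coverage policies order as incremental < all-supplemented
           < universal", {
  args <- list(child_annual_cost = 9.9, pregnancy_cost = 3.57,
               uptake_increase_child = 0.2, uptake_increase_woman = 0.17,
               uptake_baseline_child = 0.0964, uptake_baseline_woman = 0.41)
  v <- sapply(c("incremental", "all-supplemented", "universal"), function(cv)
    do.call(intervention_cost_per_child, c(args, coverage = cv)))
  expect_true(all(diff(v) > 0))
  expect_error(intervention_cost_per_child(9.9, 3.57, 0.2, 0.17,
                                           target_population = 0), "target")
})
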