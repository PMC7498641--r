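test_that("PSA with all-degenerate distributions equals the deterministic
           run", {
  reg <- fixed_registry()
  det <- cea_basecase(reg, "medium")
  p <- run_psa(reg, "medium", n_samples = 8, master_seed = 3)
  expect_true(all(abs(p$samples$delta_cost - det$delta_cost) < 1e-12))
  expect_true(all(abs(p$samples$delta_qalys - det$delta_qalys) < 1e-12))
  expect_equal(glance(p)$icer_of_means, det$icer, tolerance = 1e-12)
})

test_that("PSA mean of a linear toy model is within 3 Monte-Carlo SEs of
           the closed form", {
  reg <- tibble::tibble(name = "theta", point = 0.4, sd_reported = NA,
                        family = "beta", a = 2, b = 3,
                        lognormal_scale = "natural", source = "toy")
  lin <- function(v) list(delta_cost = 100 * v$theta, delta_qalys = v$theta)
  p <- run_psa(reg, n_samples = 1e5, master_seed = 17, model = lin,
               lambda_grid = 150)
  m <- dist_moments(dist_spec("beta", 2, 3))
  se <- m[["sd"]] / sqrt(1e5)
  expect_lt(abs(glance(p)$mean_delta_qalys - m[["mean"]]), 3 * se)
  expect_lt(abs(glance(p)$mean_delta_cost - 100 * m[["mean"]]), 300 * se)
})

test_that("PSA is reproducible under the master seed", {
  p1 <- run_psa(n_samples = 60, master_seed = 9)
  p2 <- run_psa(n_samples = 60, master_seed = 9)
  expect_identical(p1$ceac, p2$ceac)
  expect_identical(p1$samples, p2$samples)
  expect_identical(tidy(p1), p1$samples)
})

test_that("univariate sweep equals direct evaluation at the quantiles", {
  reg <- default_parameters()
  sw <- univariate_sweep(reg, "or_rickets", "medium")
  pts <- registry_points(reg)
  for (side in c("lower", "upper")) {
    q <- if (side == "lower") 0.025 else 0.975
    pts$or_rickets <- registry_quantile(reg, "or_rickets", q)
    direct <- evaluate_cea(pts, "medium")
    expect_equal(sw[[paste0("icer_", side)]], direct$icer, tolerance = 1e-12)
  }
})

test_that("fixed parameters produce flat sweeps; the medium-subgroup risk
           sweep flips the adoption decision", {
  reg <- default_parameters()
  flat <- univariate_sweep(reg, "admin_budget", "medium")
  expect_equal(flat$icer_lower, flat$icer_upper)
  expect_false(flat$decision_changed)

  risk <- univariate_sweep(reg, "risk_medium", "medium", lambda = 20000)
  expect_true(risk$decision_changed)
  expect_gt(risk$icer_lower, 20000)  # rarer rickets -> worse value
  expect_lt(risk$icer_upper, 20000)
  expect_error(univariate_sweep(reg, "no_such_param", "medium"), "unknown")
})

test_that("tornado orders parameters by NMB range width", {
  tor <- tornado(subgroup = "medium",
                 parameters = c("or_rickets", "risk_medium",
                                "rickets_duration", "mortality_rr"))
  widths <- abs(tor$nmb_upper - tor$nmb_lower)
  expect_true(all(diff(widths) <= 1e-9))
  # stage-2-only parameter is inert over the 4-year horizon
  expect_equal(widths[tor$parameter == "mortality_rr"], 0)
})

test_that("threshold search solves a linear crossing to 1e-6 relative", {
  reg <- tibble::tibble(name = "theta", point = 1, sd_reported = NA,
                        family = "fixed", a = 1, b = NA,
                        lognormal_scale = "natural", source = "toy")
  # NMB = a - b*theta with lambda*dQ - dC = 12 - 4*theta -> crossing at 3
  lin <- function(v) list(delta_cost = 4 * v$theta - 2, delta_qalys = 1e-3)
  res <- threshold_search(reg, "theta", lambda = 1e4, bracket = c(0, 10),
                          model = lin)
  expect_equal(res$sentinel, "within_range")
  expect_equal(res$crossing_value, 3, tolerance = 1e-6)
  expect_equal(res$direction, -1)
})

test_that("threshold search matches a dense grid scan on the real model", {
  reg <- default_parameters()
  res <- threshold_search(reg, "or_rickets", "medium", lambda = 20000,
                          bracket = c(0.05, 0.99))
  expect_equal(res$sentinel, "within_range")

  # brute-force oracle: scan NMB sign changes over a fine grid
  pts <- registry_points(reg)
  grid <- seq(0.05, 0.99, length.out = 2000)
  nmbs <- vapply(grid, function(v) {
    pts$or_rickets <- v
    nmb(evaluate_cea(pts, "medium"), 20000)
  }, numeric(1))
  flips <- which(diff(sign(nmbs)) != 0)
  expect_equal(length(flips), 1)
  step <- grid[2] - grid[1]
  expect_lt(abs(res$crossing_value - grid[flips]), step)
})

test_that("threshold search is invariant to bracket widening and reports
           sentinels for decision-stable parameters", {
  reg <- default_parameters()
  narrow <- threshold_search(reg, "or_rickets", "medium", lambda = 20000,
                             bracket = c(0.2, 0.9))
  wide <- threshold_search(reg, "or_rickets", "medium", lambda = 20000,
                           bracket = c(0.05, 0.99))
  expect_equal(narrow$crossing_value, wide$crossing_value,
               tolerance = 1e-5)

  # dark subgroup: savings dominate at any rickets duration, so the
  # decision never changes in-bracket (the "< 0" pattern)
  dark <- threshold_search(reg, "rickets_duration", "dark", lambda = 20000,
                           bracket = c(0.01, 50))
  expect_equal(dark$sentinel, "below_range")
  expect_true(is.na(dark$crossing_value))
})

test_that("non-monotone response is diagnosed with the parameter name", {
  reg <- tibble::tibble(name = "theta", point = 0.5, sd_reported = NA,
                        family = "fixed", a = 0.5, b = NA,
                        lognormal_scale = "natural", source = "toy")
  bump <- function(v) list(delta_cost = (v$theta - 0.5)^2, delta_qalys = 0)
  expect_error(threshold_search(reg, "theta", lambda = 1e4,
                                bracket = c(0, 1), model = bump),
               "monotone.*theta|theta.*monotone")
})
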