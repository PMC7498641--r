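test_that("baseline utility evaluates the printed algorithm and clips", {
  expect_equal(baseline_utility(0, 0), 0.950857)
  expect_equal(baseline_utility(0, 1), 0.972070)
  expect_equal(baseline_utility(10, 1), 0.950857 - 0.000259 * 100 + 0.021213)
  # the printed quadratic hits zero before old age; clipping keeps it at 0
  expect_equal(baseline_utility(80, 0), 0)
  expect_gte(baseline_utility(62, 1), 0)
  # population-norm form stays plausible at old ages
  expect_gt(baseline_utility(80, 0, form = "population_norm"), 0.5)
  expect_error(baseline_utility(-1, 0))
})

test_that("degenerate tree reduces to the discounted baseline annuity", {
  cfg <- cea_config()
  lt0 <- flat_life_table(10)
  out <- evaluate_arm(annual_risk = 0, treatment_cost = 500,
                      config = cfg, life_table = lt0)
  expect_equal(out$expected_cost, 0)
  ub <- mixed_ub(4)
  expect_equal(out$expected_qalys, sum(ub / 1.035^(0:3)), tolerance = 1e-12)
  expect_equal(out$p_alive, 1)
  expect_equal(out$p_rickets_alive, 0)
})

test_that("a 2-path single-cycle toy equals the hand-enumerated expectation", {
  h <- health_params(rickets_utility = 0.6, rickets_duration = 1)
  cfg <- cea_config(discount_rate = 0, horizon_years = 1, gender_mix = 0)
  out <- evaluate_arm(annual_risk = 0.3, treatment_cost = 1000, health = h,
                      config = cfg, life_table = flat_life_table(5))
  # p*(cost C, utility 0.6) + (1-p)*(cost 0, baseline utility)
  expect_equal(out$expected_cost, 0.3 * 1000, tolerance = 1e-12)
  expect_equal(out$expected_qalys, 0.3 * 0.6 + 0.7 * 0.950857,
               tolerance = 1e-12)
})

test_that("stage 1 equals the recursive path-enumeration oracle", {
  qx <- c(0.004, 3e-4, 3e-4, 3e-4)
  lt <- data.frame(age = 0:3, qx = qx)
  cases <- list(
    list(p = 0.02, dur = 2, ru = 0.621, tc = 2385, ic = 9.2, r = 0.035),
    list(p = 0.15, dur = 1.4, ru = 0.5, tc = 7305, ic = 0, r = 0),
    list(p = 0.0008, dur = 3.7, ru = 0.9, tc = 1750, ic = 12, r = 0.06))
  for (cs in cases) {
    h <- health_params(rickets_utility = cs$ru, rickets_duration = cs$dur)
    cfg <- cea_config(discount_rate = cs$r)
    out <- evaluate_arm(annual_risk = cs$p, treatment_cost = cs$tc,
                        intervention_cost = cs$ic, health = h, config = cfg,
                        life_table = lt)
    want <- oracle_stage1(cs$p, qx, cs$tc, cs$ic, mixed_ub(4), cs$ru,
                          cs$dur, cs$r, 4)
    expect_equal(out$expected_cost, want[["cost"]], tolerance = 1e-12)
    expect_equal(out$expected_qalys, want[["qaly"]], tolerance = 1e-12)
  }
})

test_that("mass is conserved: survival and onset bookkeeping", {
  lt <- data.frame(age = 0:3, qx = c(0.01, 0.02, 0.005, 0.003))
  out <- evaluate_arm(annual_risk = 0.1, treatment_cost = 100,
                      life_table = lt)
  # rickets does not kill: alive mass is the plain survival product
  expect_equal(out$p_alive, prod(1 - lt$qx), tolerance = 1e-12)
  tr <- tidy(out)
  expect_equal(nrow(tr), 4)
  expect_true(all(diff(tr$p_alive) < 0))
  expect_lte(out$p_rickets_alive, out$p_alive)
  expect_equal(glance(out)$cycles, 4L)
})

test_that("QALYs move monotonically with risk, OR, duration and discount", {
  base <- function(...) {
    args <- list(annual_risk = 0.05, treatment_cost = 1000)
    mods <- list(...)
    args[names(mods)] <- mods
    do.call(evaluate_arm, args)$expected_qalys
  }
  expect_gt(base(or_effect = 0.41), base(or_effect = 1))
  expect_gt(base(annual_risk = 0.01), base(annual_risk = 0.1))
  expect_gt(base(health = health_params(rickets_duration = 1)),
            base(health = health_params(rickets_duration = 3)))
  expect_gt(base(config = cea_config(discount_rate = 0)),
            base(config = cea_config(discount_rate = 0.06)))
  expect_gt(base(health = health_params(rickets_utility = 0.8)),
            base(health = health_params(rickets_utility = 0.5)))
})

test_that("lifetime extension reduces to a survival-weighted annuity when
           the stage-2 channels are off", {
  h <- health_params(complication_probability = 0,
                     deficiency_prevalence = 0)
  cfg <- cea_config(max_age = 12)
  lt <- flat_life_table(12)
  out <- evaluate_arm(annual_risk = 0, treatment_cost = 0, health = h,
                      config = cfg, life_table = lt, horizon = "lifetime")
  ub <- mixed_ub(12)
  expect_equal(out$expected_qalys, sum(ub / 1.035^(0:11)), tolerance = 1e-12)
  expect_equal(out$expected_cost, 0)
})

test_that("mortality RR of 1 leaves the survival curve unchanged by
           deficiency status", {
  cfg <- cea_config(max_age = 95)
  h0 <- health_params(deficiency_prevalence = 0, deficiency_disutility = 0,
                      mortality_rr = 1)
  h1 <- health_params(deficiency_prevalence = 1, deficiency_disutility = 0,
                      mortality_rr = 1)
  a0 <- evaluate_arm(0, 0, health = h0, config = cfg, horizon = "lifetime")
  a1 <- evaluate_arm(0, 0, health = h1, config = cfg, horizon = "lifetime")
  expect_equal(a0$expected_qalys, a1$expected_qalys, tolerance = 1e-12)
  expect_equal(a0$p_alive, a1$p_alive, tolerance = 1e-12)
})

test_that("a 3-age stage 2 matches a hand-computed cycle-by-cycle
           expectation", {
  # horizon 4, max_age 7: stage-2 ages 4, 5, 6
  h <- health_params(rickets_utility = 0.6, rickets_duration = 1,
                     complication_probability = 0.1,
                     complication_disutility = 0.05,
                     complication_annual_cost = 500,
                     deficiency_prevalence = 0.3,
                     deficiency_disutility = 0.1,
                     deficiency_onset_age = 5,
                     mortality_rr = 1.5, mortality_onset_age = 6)
  cfg <- cea_config(discount_rate = 0.035, max_age = 7, gender_mix = 0)
  qx <- c(0.004, 3e-4, 3e-4, 3e-4, 0.01, 0.02, 0.03)
  lt <- data.frame(age = 0:6, qx = qx)
  p <- 0.05
  s1 <- evaluate_arm(p, 1000, health = h, config = cfg, life_table = lt)
  out <- lifetime_extension(s1, health = h, config = cfg, life_table = lt)

  # independent cycle-by-cycle computation
  ub <- function(a) max(0.950857 - 0.000259 * a^2, 0)
  p_comp <- 0.1 * s1$p_rickets_alive
  masses <- c(p_comp * 0.3, p_comp * 0.7,
              (s1$p_alive - p_comp) * 0.3, (s1$p_alive - p_comp) * 0.7)
  comp <- c(1, 1, 0, 0); def <- c(1, 0, 1, 0)
  q_extra <- c(0, 0, 0)
  exp_q <- s1$expected_qalys; exp_c <- s1$expected_cost
  for (a in 4:6) {
    disc <- 1.035^-a
    for (j in 1:4) {
      u <- min(max(ub(a) - comp[j] * 0.05 - def[j] * 0.1 * (a >= 5), 0), 1)
      exp_q <- exp_q + disc * masses[j] * u
      exp_c <- exp_c + disc * masses[j] * comp[j] * 500
      qj <- min(qx[a + 1] * ifelse(def[j] == 1 && a >= 6, 1.5, 1), 1)
      masses[j] <- masses[j] * (1 - qj)
    }
  }
  expect_equal(out$expected_qalys, exp_q, tolerance = 1e-12)
  expect_equal(out$expected_cost, exp_c, tolerance = 1e-12)
  expect_equal(out$p_alive, sum(masses), tolerance = 1e-12)
})

test_that("life table shorter than the horizon raises an error", {
  expect_error(evaluate_arm(0.01, 100, life_table = data.frame(age = 0:1,
                                                               qx = 0)),
               "life table")
  s1 <- evaluate_arm(0.01, 100, life_table = flat_life_table(4),
                     config = cea_config(max_age = 50))
  expect_error(lifetime_extension(s1, life_table = flat_life_table(10)),
               "life table")
})
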