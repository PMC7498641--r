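#' Probabilistic sensitivity analysis
#'
#' Draws `n_samples` joint parameter sets from the registry (independent
#' across parameters, each on its own seeded sub-stream), evaluates the
#' model once per draw, and summarises the paired incremental samples.
#' Identical `master_seed` gives identical output.
#'
#' The summary reports mean incremental cost and QALYs, the ICER of the
#' means, the CEAC on the lambda grid, and quantile intervals of per-sample
#' net monetary benefit at each lambda. Per-sample ICER means are not
#' reported: the ratio is unstable near zero incremental QALYs.
#'
#' @param registry Parameter registry tibble.
#' @param subgroup Subgroup label (ignored when `model` is supplied).
#' @param n_samples Number of PSA draws (default 10,000).
#' @param master_seed Integer master seed.
#' @param config,costcfg,life_table,horizon,... As in [evaluate_cea()].
#' @param lambda_grid Willingness-to-pay grid for the CEAC; defaults to
#'   `config$lambda_grid`.
#' @param model Optional function mapping a named list of parameter values
#'   to a list/row with `delta_cost` and `delta_qalys`; defaults to the full
#'   decision-tree evaluation for `subgroup`.
#' @return An object of class `psa_result`: list with `samples` (tibble of
#'   `delta_cost`, `delta_qalys`), `ceac`, `summary` (one-row tibble),
#'   `master_seed`, `n_samples`, `subgroup`.
#' @export
run_psa <- function(registry = default_parameters(), subgroup = "medium",
                    n_samples = 10000, master_seed = 1L,
                    config = cea_config(), costcfg = cost_config(),
                    life_table = synthetic_life_table(config$max_age),
                    horizon = "base", lambda_grid = config$lambda_grid,
                    model = NULL, ...) {
  stopifnot(n_samples >= 1)
  draws <- registry_sample(registry, n_samples, master_seed)
  if (is.null(model)) {
    model <- function(values)
      evaluate_cea(values, subgroup, config = config, costcfg = costcfg,
                   life_table = life_table, horizon = horizon, ...)
  }
  samples <- purrr::map_dfr(seq_len(n_samples), function(i) {
    res <- model(as.list(draws[i, ]))
    tibble::tibble(delta_cost = res$delta_cost, delta_qalys = res$delta_qalys)
  })
  cc <- ceac(samples, lambda_grid)
  mean_dc <- mean(samples$delta_cost)
  mean_dq <- mean(samples$delta_qalys)
  nmb_ci <- purrr::map_dfr(lambda_grid, function(l) {
    v <- l * samples$delta_qalys - samples$delta_cost
    tibble::tibble(lambda = l, nmb_mean = mean(v),
                   nmb_lower = stats::quantile(v, 0.025, names = FALSE),
                   nmb_upper = stats::quantile(v, 0.975, names = FALSE))
  })
  summary <- tibble::tibble(
    subgroup = subgroup, n_samples = n_samples, master_seed = master_seed,
    mean_delta_cost = mean_dc, mean_delta_qalys = mean_dq,
    icer_of_means = ifelse(mean_dq != 0, mean_dc / mean_dq, NA_real_),
    prob_dominant = mean(samples$delta_cost < 0 & samples$delta_qalys > 0))
  structure(list(samples = samples, ceac = cc, nmb = nmb_ci,
                 summary = summary, master_seed = master_seed,
                 n_samples = n_samples, subgroup = subgroup),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf(
    "<psa_result> %s: %d samples (seed %d); mean dC %.4f, mean dQ %.6g\n",
    x$subgroup, x$n_samples, x$master_seed,
    x$summary$mean_delta_cost, x$summary$mean_delta_qalys))
  print(x$ceac)
  invisible(x)
}

#' @rdname run_psa
#' @param x A `psa_result`.
#' @export
tidy.psa_result <- function(x, ...) x$samples

#' @rdname run_psa
#' @export
glance.psa_result <- function(x, ...) x$summary

#' Univariate (tornado) sensitivity sweep
#'
#' Re-evaluates the model with one parameter set to the 2.5th and 97.5th
#' percentiles of its sampling distribution, all other parameters at their
#' point estimates, and reports the ICER at each end and whether the
#' adoption decision (NMB sign at `lambda`) flips across the range.
#'
#' @param registry Parameter registry tibble.
#' @param parameter Name of the parameter to sweep.
#' @param subgroup Subgroup label.
#' @param lambda Willingness to pay used for the flip check (default
#'   £20,000/QALY).
#' @param lower_q,upper_q Sweep quantiles (defaults 0.025, 0.975).
#' @param config,costcfg,life_table,horizon,... As in [evaluate_cea()].
#' @return One-row tibble: `parameter`, `value_lower`, `value_upper`,
#'   `icer_lower`, `icer_upper`, `status_lower`, `status_upper`,
#'   `nmb_lower`, `nmb_upper`, `decision_changed`.
#' @export
univariate_sweep <- function(registry, parameter, subgroup = "medium",
                             lambda = 20000, lower_q = 0.025, upper_q = 0.975,
                             config = cea_config(), costcfg = cost_config(),
                             life_table = synthetic_life_table(config$max_age),
                             horizon = "base", ...) {
  if (!parameter %in% registry$name)
    stop("unknown parameter: ", parameter, call. = FALSE)
  pts <- registry_points(registry)
  eval_at <- function(v) {
    pts[[parameter]] <- v
    evaluate_cea(pts, subgroup, config = config, costcfg = costcfg,
                 life_table = life_table, horizon = horizon, ...)
  }
  vals <- registry_quantile(registry, parameter, c(lower_q, upper_q))
  lo <- eval_at(vals[1]); hi <- eval_at(vals[2])
  tibble::tibble(
    parameter = parameter, subgroup = subgroup,
    value_lower = vals[1], value_upper = vals[2],
    icer_lower = lo$icer, icer_upper = hi$icer,
    status_lower = lo$status, status_upper = hi$status,
    nmb_lower = nmb(lo, lambda), nmb_upper = nmb(hi, lambda),
    decision_changed = sign(nmb(lo, lambda)) != sign(nmb(hi, lambda)))
}

#' Tornado table over several parameters
#'
#' Runs [univariate_sweep()] for each parameter and orders the result by the
#' width of the NMB range, the usual tornado-diagram ordering.
#'
#' @param registry Parameter registry tibble.
#' @param parameters Parameters to sweep; by default every non-fixed
#'   registry parameter relevant to the chosen subgroup.
#' @inheritParams univariate_sweep
#' @return Tibble of class `tornado_result`, one row per parameter.
#' @export
tornado <- function(registry = default_parameters(), parameters = NULL,
                    subgroup = "medium", lambda = 20000,
                    config = cea_config(), costcfg = cost_config(),
                    life_table = synthetic_life_table(config$max_age),
                    horizon = "base", ...) {
  if (is.null(parameters)) {
    other_sg <- setdiff(c("light", "medium", "dark"), subgroup)
    drop <- c(paste0("risk_", other_sg), paste0("cost_", other_sg))
    parameters <- setdiff(registry$name[registry$family != "fixed"], drop)
  }
  out <- purrr::map_dfr(parameters, function(pm)
    univariate_sweep(registry, pm, subgroup = subgroup, lambda = lambda,
                     config = config, costcfg = costcfg,
                     life_table = life_table, horizon = horizon, ...))
  out <- dplyr::arrange(out, dplyr::desc(abs(.data$nmb_upper - .data$nmb_lower)))
  class(out) <- c("tornado_result", class(out))
  out
}

#' Threshold analysis: parameter value at which the adoption decision
#' changes
#'
#' Bisection on the sign of net monetary benefit at `lambda` as one
#' parameter varies over `bracket`, all others held at their point
#' estimates. Operating on NMB rather than the raw ICER avoids ratio
#' instabilities near zero incremental QALYs; at the crossing the ICER
#' equals `lambda` whenever it is defined.
#'
#' Monotonicity of NMB in the parameter over the bracket is validated on a
#' coarse grid first; a non-monotone response is an error naming the
#' parameter. When NMB does not change sign inside the bracket the crossing
#' is reported as the sentinel `"below_range"` or `"above_range"`.
#'
#' @param registry Parameter registry tibble.
#' @param parameter Parameter to search over.
#' @param subgroup Subgroup label.
#' @param lambda Willingness to pay (£/QALY).
#' @param bracket Length-2 numeric search interval.
#' @param tol Relative tolerance on the crossing value (default 1e-6).
#' @param n_grid Grid points for the monotonicity pre-check (default 21).
#' @param config,costcfg,life_table,horizon,... As in [evaluate_cea()].
#' @param model Optional function mapping a named list of parameter values
#'   to a row with `delta_cost` and `delta_qalys`; defaults to the full
#'   decision-tree evaluation for `subgroup`.
#' @return One-row tibble: `parameter`, `subgroup`, `lambda`,
#'   `crossing_value` (NA when sentinel), `sentinel` (`"within_range"`,
#'   `"below_range"` or `"above_range"`), `direction` (sign of dNMB/dtheta).
#' @export
threshold_search <- function(registry, parameter, subgroup = "medium",
                             lambda = 20000, bracket, tol = 1e-6, n_grid = 21,
                             config = cea_config(), costcfg = cost_config(),
                             life_table = synthetic_life_table(config$max_age),
                             horizon = "base", model = NULL, ...) {
  if (!parameter %in% registry$name)
    stop("unknown parameter: ", parameter, call. = FALSE)
  stopifnot(length(bracket) == 2, all(is.finite(bracket)),
            bracket[1] < bracket[2])
  pts <- registry_points(registry)
  if (is.null(model)) {
    model <- function(values)
      evaluate_cea(values, subgroup, config = config, costcfg = costcfg,
                   life_table = life_table, horizon = horizon, ...)
  }
  f <- function(v) {
    pts[[parameter]] <- v
    res <- model(pts)
    nmb(res, lambda)
  }
  grid <- seq(bracket[1], bracket[2], length.out = n_grid)
  fg <- vapply(grid, f, numeric(1))
  d <- diff(fg)
  scale <- max(abs(fg), 1e-12)
  if (any(d > 1e-9 * scale) && any(d < -1e-9 * scale))
    stop(sprintf(
      "threshold_search: NMB is not monotone in '%s' over the bracket",
      parameter), call. = FALSE)
  increasing <- sum(d) >= 0
  direction <- if (increasing) 1 else -1

  f_lo <- fg[1]; f_hi <- fg[n_grid]
  if (sign(f_lo) == sign(f_hi) && f_lo != 0 && f_hi != 0) {
    # the crossing lies outside the bracket; place it by monotone direction
    sentinel <- if (increasing) {
      if (f_lo > 0) "below_range" else "above_range"
    } else {
      if (f_lo > 0) "above_range" else "below_range"
    }
    return(tibble::tibble(parameter = parameter, subgroup = subgroup,
                          lambda = lambda, crossing_value = NA_real_,
                          sentinel = sentinel, direction = direction))
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f_lo
  while (hi - lo > tol * max(abs(lo), abs(hi), 1e-300)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0) { lo <- hi <- mid; break }
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  tibble::tibble(parameter = parameter, subgroup = subgroup, lambda = lambda,
                 crossing_value = (lo + hi) / 2, sentinel = "within_range",
                 direction = direction)
}
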