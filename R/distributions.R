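#' Distribution specification for a model parameter
#'
#' Constructs the sampling distribution attached to a model parameter in the
#' probabilistic sensitivity analysis. Five families are supported:
#' `beta(a, b)` (shape1/shape2), `gamma(a, b)` (shape/scale),
#' `lognormal(a, b)`, `normal(a, b)` (mean/SD) and `fixed(a)` (degenerate at
#' `a`).
#'
#' For the lognormal family the published convention is ambiguous: source
#' tables print the natural-scale mean and SD (e.g. an odds ratio of 0.41
#' with SD 0.34) rather than the log-scale location and scale. By default
#' `(a, b)` are therefore read as the natural-scale mean and SD and
#' moment-matched to the log scale; set `lognormal_scale = "log"` to read
#' `(a, b)` as the log-scale `(meanlog, sdlog)` directly.
#'
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`, `"normal"`,
#'   `"fixed"`.
#' @param a First parameter (family-specific, see Details).
#' @param b Second parameter; ignored for `"fixed"`.
#' @param lognormal_scale `"natural"` (default) or `"log"`; only consulted for
#'   the lognormal family.
#' @return An object of class `dist_spec`.
#' @examples
#' d <- dist_spec("beta", 30.64, 18.70)
#' dist_moments(d)
#' @export
dist_spec <- function(family = c("beta", "gamma", "lognormal", "normal", "fixed"),
                      a, b = NA_real_,
                      lognormal_scale = c("natural", "log")) {
  family <- match.arg(family)
  lognormal_scale <- match.arg(lognormal_scale)
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (!is.finite(a)) stop("dist_spec: 'a' must be finite", call. = FALSE)
  switch(family,
    beta = {
      if (a <= 0 || !is.finite(b) || b <= 0)
        stop("beta requires a > 0 and b > 0", call. = FALSE)
    },
    gamma = {
      if (a <= 0 || !is.finite(b) || b <= 0)
        stop("gamma requires shape a > 0 and scale b > 0", call. = FALSE)
    },
    lognormal = {
      if (lognormal_scale == "natural" && (a <= 0 || !is.finite(b) || b < 0))
        stop("lognormal (natural scale) requires mean a > 0 and SD b >= 0",
             call. = FALSE)
      if (lognormal_scale == "log" && (!is.finite(b) || b < 0))
        stop("lognormal (log scale) requires sdlog b >= 0", call. = FALSE)
    },
    normal = {
      if (!is.finite(b) || b < 0) stop("normal requires SD b >= 0", call. = FALSE)
    },
    fixed = {
      b <- NA_real_
    }
  )
  structure(
    list(family = family, a = a, b = b, lognormal_scale = lognormal_scale),
    class = "dist_spec"
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  m <- dist_moments(x)
  cat(sprintf("<dist_spec> %s(%g%s)  mean %.6g, sd %.6g\n",
              x$family, x$a, if (is.na(x$b)) "" else sprintf(", %g", x$b),
              m[["mean"]], m[["sd"]]))
  invisible(x)
}

# (meanlog, sdlog) for a lognormal spec under either parameterisation
.lnorm_pars <- function(dist) {
  if (dist$lognormal_scale == "log") {
    c(mu = dist$a, sigma = dist$b)
  } else {
    sigma2 <- log(1 + (dist$b / dist$a)^2)
    c(mu = log(dist$a) - sigma2 / 2, sigma = sqrt(sigma2))
  }
}

#' Analytic mean and SD of a distribution specification
#'
#' @param dist A [dist_spec()].
#' @return Named numeric vector `c(mean = , sd = )`.
#' @examples
#' dist_moments(dist_spec("gamma", 100, 0.02))  # mean 2, sd 0.2
#' @export
dist_moments <- function(dist) {
  stopifnot(inherits(dist, "dist_spec"))
  a <- dist$a; b <- dist$b
  switch(dist$family,
    beta = {
      m <- a / (a + b)
      s <- sqrt(a * b / ((a + b)^2 * (a + b + 1)))
      c(mean = m, sd = s)
    },
    gamma = c(mean = a * b, sd = sqrt(a) * b),
    normal = c(mean = a, sd = b),
    lognormal = {
      p <- .lnorm_pars(dist)
      m <- exp(p[["mu"]] + p[["sigma"]]^2 / 2)
      s <- m * sqrt(exp(p[["sigma"]]^2) - 1)
      c(mean = m, sd = s)
    },
    fixed = c(mean = a, sd = 0),
    stop("unsupported family: ", dist$family, call. = FALSE)
  )
}

#' Method-of-moments fit of a distribution family
#'
#' Finds the `dist_spec` of the requested family whose analytic mean and SD
#' equal the supplied values. Inverse of [dist_moments()] on its range.
#'
#' @param mean,sd Target moments. For `"beta"` feasibility requires
#'   `sd^2 < mean * (1 - mean)`; for `"gamma"` and natural-scale
#'   `"lognormal"`, `mean > 0`.
#' @param family Distribution family name.
#' @return A [dist_spec()].
#' @examples
#' fit_from_moments(2, 0.2, "gamma")  # gamma(100, 0.02)
#' @export
fit_from_moments <- function(mean, sd, family = c("beta", "gamma", "lognormal",
                                                  "normal", "fixed")) {
  family <- match.arg(family)
  switch(family,
    beta = {
      if (mean <= 0 || mean >= 1)
        stop("beta fit requires mean in (0,1)", call. = FALSE)
      if (sd^2 >= mean * (1 - mean))
        stop(sprintf(
          "beta fit infeasible: sd^2 = %.4g must be < mean(1-mean) = %.4g",
          sd^2, mean * (1 - mean)), call. = FALSE)
      nu <- mean * (1 - mean) / sd^2 - 1
      dist_spec("beta", mean * nu, (1 - mean) * nu)
    },
    gamma = {
      if (mean <= 0 || sd <= 0)
        stop("gamma fit requires mean > 0 and sd > 0", call. = FALSE)
      dist_spec("gamma", (mean / sd)^2, sd^2 / mean)
    },
    lognormal = {
      if (mean <= 0)
        stop("lognormal fit requires mean > 0", call. = FALSE)
      dist_spec("lognormal", mean, sd, lognormal_scale = "natural")
    },
    normal = dist_spec("normal", mean, sd),
    fixed = {
      if (sd != 0) stop("fixed fit requires sd = 0", call. = FALSE)
      dist_spec("fixed", mean)
    }
  )
}

#' Draw a reproducible sample from a distribution specification
#'
#' Seeding is local: the caller's RNG state is saved and restored, so sampling
#' never perturbs other random draws in the session.
#'
#' @param dist A [dist_spec()].
#' @param n Number of draws (`n >= 1`).
#' @param seed Optional integer seed; identical seeds give identical vectors.
#' @return Numeric vector of length `n`.
#' @export
dist_sample <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "dist_spec"), n >= 1)
  draw <- function() {
    switch(dist$family,
      beta = stats::rbeta(n, dist$a, dist$b),
      gamma = stats::rgamma(n, shape = dist$a, scale = dist$b),
      normal = stats::rnorm(n, dist$a, dist$b),
      lognormal = {
        p <- .lnorm_pars(dist)
        stats::rlnorm(n, p[["mu"]], p[["sigma"]])
      },
      fixed = rep(dist$a, n)
    )
  }
  if (is.null(seed)) return(draw())
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  draw()
}

#' Quantile (inverse CDF) of a distribution specification
#'
#' @param dist A [dist_spec()].
#' @param p Probability (or vector of probabilities) strictly in (0, 1).
#' @return Numeric vector of quantiles, monotone non-decreasing in `p`.
#' @export
dist_quantile <- function(dist, p) {
  stopifnot(inherits(dist, "dist_spec"))
  if (any(p <= 0 | p >= 1))
    stop("quantile requires p strictly in (0, 1)", call. = FALSE)
  switch(dist$family,
    beta = stats::qbeta(p, dist$a, dist$b),
    gamma = stats::qgamma(p, shape = dist$a, scale = dist$b),
    normal = stats::qnorm(p, dist$a, dist$b),
    lognormal = {
      pr <- .lnorm_pars(dist)
      stats::qlnorm(p, pr[["mu"]], pr[["sigma"]])
    },
    fixed = rep(dist$a, length(p))
  )
}
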