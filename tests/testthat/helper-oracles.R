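# Independent brute-force oracles used across test files. These deliberately
# share no code with the package internals: the tree oracle enumerates paths
# recursively, the stage-2 oracle steps cohorts one cycle at a time.

# Expected (cost, qalys) of the stage-1 tree by recursive path enumeration.
# p: annual onset probability; qx: per-cycle death probabilities (length T);
# ub: per-cycle baseline utilities (length T); onset at cycle start, cost at
# onset, death at cycle end, discounting (1+r)^-(t+offset).
oracle_stage1 <- function(p, qx, tc, ic, ub, ru, dur, r, T, offset = 0) {
  rec <- function(t, onset) {
    if (t == T) return(c(cost = 0, qaly = 0))
    disc <- (1 + r)^-(t + offset)
    total <- c(cost = 0, qaly = 0)
    branches <- if (is.na(onset)) {
      list(list(pr = p, o = t), list(pr = 1 - p, o = NA))
    } else list(list(pr = 1, o = onset))
    for (b in branches) {
      u <- if (!is.na(b$o)) {
        frac <- min(max(dur - (t - b$o), 0), 1)
        frac * ru + (1 - frac) * ub[t + 1]
      } else ub[t + 1]
      c_t <- if (!is.na(b$o) && b$o == t) tc else 0
      here <- c(cost = disc * c_t, qaly = disc * u)
      cont <- (1 - qx[t + 1]) * rec(t + 1, b$o)
      total <- total + b$pr * (here + cont)
    }
    total
  }
  out <- rec(0, NA)
  out["cost"] <- out["cost"] + ic
  out
}

# mixed-gender baseline utilities for ages 0..(T-1), printed algorithm
mixed_ub <- function(T, mix = 0.5) {
  ages <- 0:(T - 1)
  male <- pmin(pmax(0.950857 - 0.000259 * ages^2 + 0.021213, 0), 1)
  female <- pmin(pmax(0.950857 - 0.000259 * ages^2, 0), 1)
  mix * male + (1 - mix) * female
}

# a zero-mortality life table
flat_life_table <- function(max_age = 100, qx = 0) {
  data.frame(age = 0:(max_age - 1), qx = qx)
}

# registry where every distribution is degenerate at the point estimate
fixed_registry <- function(registry = default_parameters()) {
  registry$family <- "fixed"
  registry$a <- registry$point
  registry$b <- NA_real_
  registry
}
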