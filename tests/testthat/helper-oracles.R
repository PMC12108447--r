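# Independent numerical oracles used across the suite.

# Dense-grid time-above oracle: evaluates the steady-state free profile on a
# fine grid (midpoint rule) and counts the fraction of the interval above
# the threshold, replacing the closed-form crossing-time computation.
grid_percent_above <- function(ke, cmax, cmin, tau, tinf, thr, dt = 0.001) {
  t <- seq(dt / 2, tau, by = dt)
  if (tinf >= tau) {
    conc <- rep(cmax, length(t))
  } else {
    ek <- exp(-ke * tinf)
    A <- (cmax - cmin * ek) / (1 - ek)
    conc <- ifelse(t <= tinf,
                   A + (cmin - A) * exp(-ke * t),
                   cmax * exp(-ke * (t - tinf)))
  }
  100 * mean(conc > thr)
}

# Multi-dose superposition oracle: concentration at time t within the
# interval after n_dose repeated zero-order infusions (one-compartment,
# first-order elimination), built from the single-dose response only.
superpose_conc <- function(cl, v, dose, tau, tinf, t, n_dose = 60) {
  ke <- cl / v
  one <- function(td) {  # single-dose concentration at time-since-dose td
    rate <- dose / tinf
    ifelse(td < 0, 0,
           ifelse(td <= tinf,
                  rate / cl * (1 - exp(-ke * td)),
                  rate / cl * (1 - exp(-ke * tinf)) *
                    exp(-ke * (td - tinf))))
  }
  tot <- 0
  for (k in 0:(n_dose - 1)) tot <- tot + one(t + k * tau)
  tot
}

# Random steady-state scenarios for the oracle-equivalence checks.
random_pk_scenarios <- function(n, seed) {
  set.seed(seed)
  cl <- stats::runif(n, 1, 20)
  v <- stats::runif(n, 8, 50)
  tau <- sample(c(6, 8, 12, 24), n, replace = TRUE)
  tinf <- pmin(sample(c(0.5, 1, 3, 4), n, replace = TRUE), tau / 2)
  dose <- sample(c(500, 1000, 2000, 4000), n, replace = TRUE)
  ss <- steady_state_conc(cl, v, dose, tau, tinf)
  # thresholds spanning below-trough to above-peak
  thr <- exp(stats::runif(n, log(0.5 * ss$cmin + 1e-6),
                          log(1.3 * ss$cmax)))
  data.frame(ke = ss$ke, cmax = ss$cmax, cmin = ss$cmin, tau = tau,
             tinf = tinf, thr = thr)
}

# One large default cohort shared by the acceptance tests (built once).
.acc_cache <- new.env(parent = emptyenv())
acceptance_cohort <- function(n = 50000L, seed = 1L) {
  key <- paste0("coh_", n, "_", seed)
  if (is.null(.acc_cache[[key]])) {
    .acc_cache[[key]] <- generate_cohort(
      cohort_config(seed = seed, n_episodes = n))
  }
  .acc_cache[[key]]
}
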