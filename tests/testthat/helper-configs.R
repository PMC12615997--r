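# Shared simulator configurations for the tests.
#
# Problem sizes are chosen so that property and calibration studies run
# in seconds to a few minutes on one CPU while keeping per-year
# person-years at registry-like magnitudes where a test's statistical
# claim depends on them.

one_era <- function(start = 1980L, n_years = 3L, label = "pre") {
  data.frame(label = label, start = start, end = start + n_years - 1L,
             stringsAsFactors = FALSE)
}

two_eras_short <- function(n_years = 3L) {
  data.frame(label = c("pre_psa", "psa"),
             start = c(1980L, 2000L),
             end = c(1980L + n_years - 1L, 2000L + n_years - 1L),
             stringsAsFactors = FALSE)
}

# Small 2-band configuration for fast unit-level checks.
tiny_config <- function(seed = 1, ...) {
  args <- list(
    age_groups = c("45-49", "50-54"),
    eras = one_era(),
    person_years = c(white = 2e5, black = 2e5),
    white_incidence = c(100, 150),
    rr_incidence_intercept = 2, rr_incidence_slope = 0,
    white_death_prob = c(0.4, 0.45),
    rr_death_intercept = 1.2, rr_death_slope = 0,
    era_incidence_multiplier = 1, era_death_prob_multiplier = 1,
    other_cause_hazard = c(0.02, 0.03),
    followup_cutoff_year = 2012L,
    window_years = 10L,
    seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# No-disparity configuration: both races share rates and fatality, so
# every true ratio is exactly 1 and all true trend coefficients are 0.
null_config <- function(seed = 1, n_ages = 8L) {
  sim_config(
    age_groups = default_age_groups()[seq_len(n_ages)],
    eras = two_eras_short(),
    person_years = c(white = 1e5, black = 5e4),
    white_incidence = rep(200, n_ages),
    rr_incidence_intercept = 1, rr_incidence_slope = 0,
    white_death_prob = rep(0.3, n_ages),
    rr_death_intercept = 1, rr_death_slope = 0,
    era_incidence_multiplier = c(1, 1), era_death_prob_multiplier = c(1, 1),
    other_cause_hazard = rep(0.02, n_ages),
    followup_cutoff_year = 2012L,
    window_years = 10L,
    seed = seed)
}

# Four-band variant of tiny_config for tests that need a fit-able
# age trend but small strata.
small4_config <- function(seed = 1, ...) {
  tiny_config(seed = seed,
              age_groups = c("45-49", "50-54", "55-59", "60-64"),
              white_incidence = c(100, 150, 200, 250),
              white_death_prob = c(0.4, 0.45, 0.5, 0.55),
              other_cause_hazard = c(0.02, 0.03, 0.04, 0.05),
              ...)
}

# Registry-scale person-years (as in the default configuration) on a
# reduced 4-band, one-era grid: used where a calibration claim is about
# registry-sized strata but the full grid would be needlessly slow.
midsize_config <- function(seed = 1) {
  sim_config(
    age_groups = c("55-59", "60-64", "65-69", "70-74"),
    eras = one_era(),
    person_years = c(white = 6e5, black = 8e4),
    white_incidence = c(100, 200, 350, 500),
    rr_incidence_intercept = 2.2, rr_incidence_slope = -0.06,
    white_death_prob = c(0.31, 0.34, 0.37, 0.40),
    rr_death_intercept = 1.49, rr_death_slope = -0.008,
    era_incidence_multiplier = 1, era_death_prob_multiplier = 1,
    other_cause_hazard = c(0.02, 0.028, 0.04, 0.055),
    followup_cutoff_year = 2012L,
    window_years = 10L,
    seed = seed)
}

# Independent product-limit oracle: a sequential risk-set walk over
# increasing unique times, deaths processed before censorings at ties.
# Written for clarity, not speed; only used on small strata.
pl_oracle <- function(time, status, window) {
  s <- 1
  gw <- 0
  at_risk <- length(time)
  for (t in sort(unique(time))) {
    d <- sum(time == t & status == 1)
    c_ <- sum(time == t & status == 0)
    if (t <= window && d > 0) {
      s <- s * (1 - d / at_risk)
      if (at_risk > d) gw <- gw + d / (at_risk * (at_risk - d))
    }
    at_risk <- at_risk - d - c_
  }
  list(survival = s, variance = if (s > 0) s^2 * gw else 0)
}

# Brute-force weighted least squares by the normal equations.
wls_oracle <- function(X, y, w) {
  XtW <- t(X * w)
  beta <- solve(XtW %*% X, XtW %*% y)
  resid <- y - X %*% beta
  sigma2 <- sum(w * resid^2) / (length(y) - ncol(X))
  list(beta = drop(beta), vcov = solve(XtW %*% X) * sigma2)
}

# One full synthetic pipeline pass without file output.
run_synthetic <- function(cfg) {
  reg <- simulate_registry(cfg)
  inc <- estimate_incidence(reg$cases, reg$population)
  srv <- estimate_survival(reg$cases, cfg$window_years)
  list(registry = reg, incidence = inc, survival = srv,
       ratios = decompose(inc, srv))
}
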