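mk_ratios <- function(rr, log_se, age = seq_along(rr) - 1L, era = "pre",
                      metric = "incidence") {
  data.frame(metric = metric, era = era, age_group_index = age,
             rr = rr, log_se = log_se, stringsAsFactors = FALSE)
}

test_that("ratios lying exactly on a line are fitted to machine precision", {
  k <- 0:7
  m <- fit_trend(mk_ratios(2.2 - 0.1 * k, rep(0.05, 8)), weights = "equal")
  expect_equal(m$coefficients[["intercept"]], 2.2, tolerance = 1e-12)
  expect_equal(m$coefficients[["age_slope"]], -0.1, tolerance = 1e-12)
})

test_that("identical ratio vectors in both eras give zero era terms", {
  k <- 0:7
  rr <- 2.5 - 0.08 * k + c(0.02, -0.01, 0, 0.01, -0.02, 0, 0.01, -0.01)
  rat <- rbind(mk_ratios(rr, rep(0.05, 8), era = "pre"),
               mk_ratios(rr, rep(0.05, 8), era = "post"))
  m <- fit_trend(rat, weights = "equal")
  expect_equal(m$coefficients[["era_shift"]], 0, tolerance = 1e-10)
  expect_equal(m$coefficients[["age_era_interaction"]], 0, tolerance = 1e-10)
})

test_that("the weighted fit equals the brute-force normal equations on toy designs", {
  # 4-point toy with strongly unequal weights
  k <- 0:3
  rr <- c(3.0, 2.5, 2.1, 1.6)
  w <- c(4, 1, 1, 4)
  log_se <- sqrt(1 / (w * rr^2))  # so that 1/(rr^2 log_se^2) = w
  m <- fit_trend(mk_ratios(rr, log_se, age = k), weights = "invvar")
  o <- wls_oracle(cbind(1, k), rr, w)
  expect_equal(unname(m$coefficients), unname(o$beta), tolerance = 1e-10)
  expect_equal(unname(m$vcov), unname(o$vcov), tolerance = 1e-10)

  # two-era toy with interaction design
  set.seed(2)
  k2 <- rep(0:4, 2)
  era <- rep(c("pre", "post"), each = 5)
  rr2 <- c(3.0, 2.6, 2.4, 2.1, 1.9, 2.7, 2.55, 2.3, 2.15, 1.8) +
    round(stats::runif(10, -0.05, 0.05), 3)
  w2 <- c(5, 2, 1, 2, 5, 1, 3, 2, 3, 1)
  rat <- mk_ratios(rr2, sqrt(1 / (w2 * rr2^2)), age = k2)
  rat$era <- era
  m2 <- fit_trend(rat, weights = "invvar", ref_era = "pre")
  X <- cbind(1, k2, era == "post", k2 * (era == "post"))
  o2 <- wls_oracle(X, rr2, w2)
  expect_equal(unname(m2$coefficients), unname(o2$beta), tolerance = 1e-10)
  expect_equal(unname(m2$vcov), unname(o2$vcov), tolerance = 1e-10)
  # Wald p-values from the t distribution with n - 4 df
  tt <- o2$beta / sqrt(diag(o2$vcov))
  expect_equal(unname(m2$p), unname(2 * stats::pt(abs(tt), 6, lower.tail = FALSE)),
               tolerance = 1e-10)
})

test_that("coefficients and p-values are invariant to rescaling all weights", {
  k <- 0:7
  rr <- 2.2 * exp(-0.06 * k)
  rat <- mk_ratios(rr, rep(0.1, 8))
  m1 <- fit_trend(rat, weights = "invvar")
  rat2 <- rat
  rat2$log_se <- rat$log_se * 7  # scales every weight by 1/49
  m2 <- fit_trend(rat2, weights = "invvar")
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-12)
  expect_equal(m1$p, m2$p, tolerance = 1e-12)
})

test_that("equal weights reproduce ordinary least squares", {
  k <- 0:7
  set.seed(13)
  rr <- 2.2 - 0.1 * k + stats::rnorm(8, 0, 0.05)
  rat <- mk_ratios(rr, stats::runif(8, 0.02, 0.3))
  m <- fit_trend(rat, weights = "equal")
  ols <- stats::lm(rr ~ k)
  expect_equal(unname(m$coefficients),
               unname(stats::coef(ols)), tolerance = 1e-12)
})

test_that("the covariance matrix is symmetric with non-negative diagonal", {
  out <- run_synthetic(tiny_config(
    seed = 19, age_groups = default_age_groups(),
    white_incidence = rep(150, 8), white_death_prob = rep(0.35, 8),
    other_cause_hazard = rep(0.03, 8)))
  m <- fit_trend(out$ratios[out$ratios$metric == "fatal", ])
  expect_equal(m$vcov, t(m$vcov), tolerance = 1e-12)
  expect_true(all(diag(m$vcov) >= 0))
  expect_identical(m$n_obs, 8L)
})

test_that("under-identified or malformed ratio tables are rejected", {
  expect_error(fit_trend(mk_ratios(c(2, 1.9), rep(0.1, 2))),
               "at least")
  rat <- mk_ratios(rep(2, 6), rep(0.1, 6), age = rep(0L, 6))
  expect_error(fit_trend(rat), "fewer than 2 age groups")
  mixed <- rbind(mk_ratios(2.2 - 0.1 * (0:7), rep(0.1, 8)),
                 mk_ratios(1.5 - 0.01 * (0:7), rep(0.1, 8),
                           metric = "death_prob"))
  expect_error(fit_trend(mixed), "mixes metrics")
})

test_that("per-era lines derive from the interaction parameterisation", {
  k <- 0:7
  rat <- rbind(mk_ratios(2.2 - 0.10 * k, rep(0.05, 8), era = "pre"),
               mk_ratios(1.9 - 0.06 * k, rep(0.05, 8), era = "post"))
  m <- fit_trend(rat, weights = "equal", ref_era = "pre")
  lines <- trend_lines(m)
  expect_equal(lines$intercept[lines$era == "pre"], 2.2, tolerance = 1e-10)
  expect_equal(lines$slope[lines$era == "pre"], -0.10, tolerance = 1e-10)
  expect_equal(lines$intercept[lines$era == "post"], 1.9, tolerance = 1e-10)
  expect_equal(lines$slope[lines$era == "post"], -0.06, tolerance = 1e-10)
})
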