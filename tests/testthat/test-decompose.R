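mk_inc <- function(rate, var, cases = 100, py = 1e6) {
  data.frame(cases = cases, person_years = py, rate = rate, variance = var,
             degenerate = cases == 0)
}
mk_surv <- function(s, var) data.frame(survival = s, variance = var)

test_that("fatal incidence obeys the composite identity in edge cases", {
  # perfect survival: no fatal cases regardless of incidence
  f <- fatal_incidence(mk_inc(100, 25), mk_surv(1, 0))
  expect_identical(f$value, 0)
  # all fatal: the incidence and its variance pass through
  f <- fatal_incidence(mk_inc(100, 25), mk_surv(0, 0))
  expect_identical(f$value, 100)
  expect_identical(f$variance, 25)
})

test_that("the delta-method variance of fatal incidence matches the closed form and a Monte-Carlo oracle", {
  # I = 80 (Var 16), S = 0.75 (Var 4e-4):
  # F = 20; Var(F) = 0.25^2*16 + 80^2*4e-4 = 1 + 2.56 = 3.56
  f <- fatal_incidence(mk_inc(80, 16), mk_surv(0.75, 4e-4))
  expect_identical(f$value, 20)
  expect_equal(f$variance, 3.56, tolerance = 1e-12)

  # independent normal perturbations of I and S propagate to Var(F);
  # the exact variance of I*(1-S) for independent normals is
  # delta + Var(I)*Var(S), here 3.56 + 0.0064
  set.seed(4)
  n <- 1e5
  i_draw <- stats::rnorm(n, 80, 4)
  s_draw <- stats::rnorm(n, 0.75, 0.02)
  mc <- stats::var(i_draw * (1 - s_draw))
  expect_lt(abs(mc - f$variance) / f$variance, 0.05)
})

test_that("stratum-keyed inputs must match", {
  inc <- cbind(data.frame(race = "white", age_group_index = 0L, era = "pre"),
               mk_inc(80, 16))
  srv <- cbind(data.frame(race = "white", age_group_index = 1L, era = "pre"),
               mk_surv(0.75, 4e-4))
  expect_error(fatal_incidence(inc, srv), "do not match")
})

test_that("rate ratios follow the log-scale delta method closed form", {
  # identical estimates: ratio 1, CI straddles 1
  r <- rate_ratio(10, 4, 10, 4)
  expect_identical(r$rr, 1)
  expect_true(r$ci_low < 1 && r$ci_high > 1)

  # Poisson counts 200 vs 100 on equal person-years: rr = 2 and
  # log SE reduces to sqrt(1/200 + 1/100)
  ib <- incidence_rate(200, 1e6)
  iw <- incidence_rate(100, 1e6)
  r <- rate_ratio(ib$rate, ib$variance, iw$rate, iw$variance)
  expect_identical(r$rr, 2)
  expect_equal(r$log_se, sqrt(1 / 200 + 1 / 100), tolerance = 1e-12)
  expect_equal(r$ci_low, 2 * exp(-stats::qnorm(0.975) * r$log_se),
               tolerance = 1e-12)
  expect_equal(r$ci_high, 2 * exp(stats::qnorm(0.975) * r$log_se),
               tolerance = 1e-12)
})

test_that("zero or negative estimates yield degenerate, not corrected, ratios", {
  r <- rate_ratio(0, 0, 10, 1)
  expect_true(r$degenerate)
  expect_true(is.na(r$rr))
  r <- rate_ratio(10, 1, 0, 0)
  expect_true(r$degenerate)
})

test_that("the fatal ratio factorises exactly into incidence and death-probability ratios", {
  set.seed(21)
  for (i in 1:25) {
    ib <- stats::runif(1, 5, 500); iw <- stats::runif(1, 5, 500)
    sb <- stats::runif(1, 0.05, 0.95); sw <- stats::runif(1, 0.05, 0.95)
    rr_inc <- ib / iw
    rr_death <- (1 - sb) / (1 - sw)
    rr_fatal <- (ib * (1 - sb)) / (iw * (1 - sw))
    expect_equal(rr_fatal, rr_inc * rr_death, tolerance = 1e-12)
  }
  # and on a full decomposition table
  out <- run_synthetic(tiny_config(seed = 14))
  wide <- split(out$ratios, out$ratios$metric)
  expect_equal(wide$fatal$rr, wide$incidence$rr * wide$death_prob$rr,
               tolerance = 1e-12)
})

test_that("the decomposition covers the full metric x age x era grid", {
  cfg <- null_config(seed = 6)
  out <- run_synthetic(cfg)
  expect_identical(nrow(out$ratios), 3L * 8L * 2L)
  expect_identical(sort(unique(out$ratios$metric)),
                   c("death_prob", "fatal", "incidence"))
  # no-disparity configuration: every ratio within sampling error of 1
  ok <- !out$ratios$degenerate
  z <- abs(log(out$ratios$rr[ok])) / out$ratios$log_se[ok]
  expect_lt(max(z), 5)
})

test_that("rate ratios are invariant to a common person-years rescaling", {
  out <- run_synthetic(tiny_config(seed = 23))
  inc2 <- out$incidence
  inc2$person_years <- inc2$person_years * 10
  inc2$rate <- 1e5 * inc2$cases / inc2$person_years
  inc2$variance <- 1e10 * inc2$cases / inc2$person_years^2
  r1 <- decompose(out$incidence, out$survival)
  r2 <- decompose(inc2, out$survival)
  expect_equal(r2$rr, r1$rr, tolerance = 1e-12)
  expect_equal(r2$log_se, r1$log_se, tolerance = 1e-12)
})

test_that("degenerate strata are emitted flagged rather than dropped", {
  inc <- data.frame(race = c("white", "black"), age_group_index = 0L,
                    era = "pre", cases = c(0L, 10L),
                    person_years = 1e5,
                    rate = c(0, 10), variance = c(0, 1),
                    degenerate = c(TRUE, FALSE))
  srv <- data.frame(race = c("white", "black"), age_group_index = 0L,
                    era = "pre", survival = c(0.8, 0.7),
                    variance = c(1e-4, 1e-4))
  out <- decompose(inc, srv)
  expect_identical(nrow(out), 3L)
  expect_true(all(out$degenerate[out$metric != "death_prob"]))
  expect_false(any(out$degenerate[out$metric == "death_prob"]))
})
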