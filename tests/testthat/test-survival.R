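mk_records <- function(time, outcome) {
  data.frame(followup_years = time, outcome = outcome,
             stringsAsFactors = FALSE)
}

test_that("all-censored and single-event strata give the textbook values", {
  # five subjects alive beyond the window: S = 1, variance 0
  r <- net_survival(mk_records(rep(12, 5), rep("alive_at_cutoff", 5)), 10)
  expect_identical(r$survival, 1)
  expect_identical(r$variance, 0)
  expect_identical(r$n_events, 0L)

  # one cancer death at 3y among two subjects, no censoring before it
  r <- net_survival(mk_records(c(3, 12), c("cancer_death", "alive_at_cutoff")), 10)
  expect_identical(r$survival, 0.5)
})

test_that("the product-limit estimate matches the hand-computed 4-record oracle", {
  # cancer death at 2y (risk 4): S = 3/4; other-cause death at 4y
  # censors; cancer death at 6y (risk 2): S = 3/8 = 0.375.
  # Greenwood: S^2 * (1/(4*3) + 1/(2*1)) = (9/64)*(7/12) = 21/256.
  rec <- mk_records(c(2, 4, 6, 12),
                    c("cancer_death", "other_death", "cancer_death",
                      "alive_at_cutoff"))
  r <- net_survival(rec, 10)
  expect_equal(r$survival, 0.375, tolerance = 1e-12)
  expect_equal(r$variance, 21 / 256, tolerance = 1e-12)
  expect_identical(r$n_initial, 4L)
  expect_identical(r$n_events, 2L)
  expect_false(r$flagged)
})

test_that("with no censoring the estimate equals one minus the death fraction exactly", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    t_death <- stats::runif(n, 0, 15)
    dead <- t_death <= 10
    rec <- mk_records(pmin(t_death, 12),
                      ifelse(dead, "cancer_death", "alive_at_cutoff"))
    rec$followup_years[!dead] <- 12  # everyone followed past the window
    r <- net_survival(rec, 10)
    expect_equal(r$survival, 1 - mean(dead), tolerance = 1e-12)
  }
})

test_that("estimates agree with an exhaustive small-sample oracle and with survival::survfit", {
  skip_if_not_installed("survival")
  set.seed(77)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    # discrete times force ties between deaths and censorings
    time <- sample(c(1:12, 2.5, 7.5), n, replace = TRUE)
    status <- stats::rbinom(n, 1, 0.5)
    rec <- mk_records(time, ifelse(status == 1, "cancer_death", "other_death"))
    r <- net_survival(rec, 10)

    o <- pl_oracle(time, status, 10)
    expect_equal(r$survival, o$survival, tolerance = 1e-12)
    expect_equal(r$variance, o$variance, tolerance = 1e-12)

    if (any(status == 1 & time <= 10) && r$survival > 0) {
      sf <- survival::survfit(survival::Surv(time, status) ~ 1)
      sm <- summary(sf, times = 10, extend = TRUE)
      expect_equal(r$survival, sm$surv, tolerance = 1e-12)
      expect_equal(sqrt(r$variance), sm$std.err, tolerance = 1e-10)
    }
  }
})

test_that("adding one cancer death never increases survival", {
  set.seed(55)
  for (i in 1:30) {
    n <- sample(3:10, 1)
    time <- stats::runif(n, 0, 14)
    status <- stats::rbinom(n, 1, 0.4)
    rec <- mk_records(time, ifelse(status == 1, "cancer_death", "other_death"))
    base <- net_survival(rec, 10)$survival
    extra <- rbind(rec, mk_records(stats::runif(1, 0, 10), "cancer_death"))
    expect_lte(net_survival(extra, 10)$survival, base + 1e-12)
  }
})

test_that("risk-set exhaustion before the window carries the last value and flags it", {
  rec <- mk_records(c(2, 5), c("cancer_death", "other_death"))
  r <- net_survival(rec, 10)
  expect_identical(r$survival, 0.5)
  expect_true(r$flagged)

  expect_error(net_survival(mk_records(numeric(), character()), 10),
               "empty stratum")
})

test_that("the actuarial estimator matches a hand-computed annual life table", {
  # interval (0,1]: 10 at risk, 1 death, 1 withdrawal: q = 1/9.5
  # interval (1,2]: 8 at risk, 2 deaths: q = 2/8
  # S(2) = (1 - 1/9.5) * (1 - 2/8)
  rec <- mk_records(c(0.5, 0.7, rep(1.5, 2), rep(3, 6)),
                    c("cancer_death", "other_death", "cancer_death",
                      "cancer_death", rep("alive_at_cutoff", 6)))
  r <- net_survival(rec, 2, method = "actuarial")
  s_hand <- (1 - 1 / 9.5) * (1 - 2 / 8)
  v_hand <- s_hand^2 * (1 / (9.5 * 8.5) + 2 / (8 * 6))
  expect_equal(r$survival, s_hand, tolerance = 1e-12)
  expect_equal(r$variance, v_hand, tolerance = 1e-12)
})

test_that("actuarial and product-limit estimates agree closely on large strata", {
  cfg <- tiny_config(seed = 17)
  cases <- simulate_registry(cfg)$cases
  sub <- cases[cases$race == "white" & cases$age_group_index == 0L, ]
  km <- net_survival(sub, 10, method = "km")
  ac <- net_survival(sub, 10, method = "actuarial")
  expect_lt(abs(km$survival - ac$survival), 0.01)
})

test_that("death probability is the exact complement with unchanged variance", {
  rec <- mk_records(c(2, 4, 6, 12),
                    c("cancer_death", "other_death", "cancer_death",
                      "alive_at_cutoff"))
  s <- net_survival(rec, 10)
  p <- death_probability(s)
  expect_identical(p$death_prob, 1 - s$survival)
  expect_identical(p$death_prob_variance, s$variance)
})

test_that("per-stratum survival estimation covers every stratum of a registry", {
  cfg <- tiny_config(seed = 9)
  reg <- simulate_registry(cfg)
  srv <- estimate_survival(reg$cases, 10)
  expect_identical(nrow(srv), 4L)  # 2 races x 2 bands x 1 era
  expect_true(all(srv$survival >= 0 & srv$survival <= 1))
  expect_true(all(srv$variance >= 0))
  one <- reg$cases[reg$cases$race == "black" & reg$cases$age_group_index == 1L, ]
  direct <- net_survival(one, 10)
  expect_equal(srv$survival[srv$race == "black" & srv$age_group_index == 1L],
               direct$survival, tolerance = 1e-15)
})
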