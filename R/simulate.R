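# Synthetic SEER-like registry with known ground truth.

# Deterministic sub-stream seed per (race, age, year) stratum, derived from
# the root seed with a Lehmer-style hash so adding strata to a configuration
# never perturbs the draws of existing ones. All arithmetic stays below 2^53
# so it is exact in doubles; the result lies in [1, 2^31 - 2].
stratum_seed <- function(seed, race_code, age_index, year) {
  m <- 2147483647
  x <- (as.double(seed) %% m + m) %% m
  for (v in c(race_code + 1, age_index + 1, year)) {
    x <- (x * 48271 + as.double(v)) %% m
  }
  as.integer(x %% (m - 1) + 1)
}

# Per-stratum generating parameters on the truth scale.
truth_params <- function(cfg) {
  n_age <- length(cfg$age_groups)
  k <- seq_len(n_age) - 1L
  grid <- expand.grid(age_group_index = k,
                      era = cfg$eras$label,
                      stringsAsFactors = FALSE)
  e_idx <- match(grid$era, cfg$eras$label)
  rr_i <- cfg$rr_incidence_intercept * exp(cfg$rr_incidence_slope * grid$age_group_index)
  rr_p <- cfg$rr_death_intercept * exp(cfg$rr_death_slope * grid$age_group_index)
  inc_w <- cfg$white_incidence[grid$age_group_index + 1L] * cfg$era_incidence_multiplier[e_idx]
  p_w <- cfg$white_death_prob[grid$age_group_index + 1L] * cfg$era_death_prob_multiplier[e_idx]
  data.frame(grid,
             age_group = cfg$age_groups[grid$age_group_index + 1L],
             incidence_white = inc_w,
             incidence_black = inc_w * rr_i,
             death_prob_white = p_w,
             death_prob_black = p_w * rr_p,
             stringsAsFactors = FALSE)
}

#' Ground-truth table for a simulation configuration
#'
#' Evaluates the generating model of [sim_config()] on every
#' age-band x era stratum: true incidence per 100,000 and true window
#' death probability for each race, the true fatal incidence (their
#' product, exactly), and the true Black/White ratio of each metric.
#'
#' @param cfg A `sim_config` object.
#' @return A data.frame with one row per age band x era.
#' @export
truth_table <- function(cfg) {
  tr <- truth_params(cfg)
  tr$fatal_white <- tr$incidence_white * tr$death_prob_white
  tr$fatal_black <- tr$incidence_black * tr$death_prob_black
  tr$rr_incidence <- tr$incidence_black / tr$incidence_white
  tr$rr_death_prob <- tr$death_prob_black / tr$death_prob_white
  tr$rr_fatal <- tr$rr_incidence * tr$rr_death_prob
  tr
}

#' Simulate a synthetic registry
#'
#' Generates individual-level case records emulating a SEER-like cancer
#' registry. For every race x age-band x diagnosis-year stratum the case
#' count is a Poisson draw with mean person-years x incidence rate. Each
#' case receives a latent cancer-death time, exponential with rate
#' `-log(1 - p_k) / k` so that the probability of cancer death within the
#' k-year window equals the configured value in the absence of competing
#' events, and an independent latent other-cause death time, exponential
#' with the configured annual hazard. The earlier of the two latent times
#' and the administrative cutoff determines follow-up and outcome.
#' Diagnoses are placed at the start of the diagnosis year, so the
#' administrative follow-up limit is `followup_cutoff_year - dx_year + 1`
#' years.
#'
#' Randomness is fully determined by `cfg$seed`: each stratum draws from
#' its own deterministically derived sub-stream, so the same seed yields
#' byte-identical output and adding strata leaves existing ones
#' untouched. The caller's RNG state is preserved.
#'
#' @param cfg A `sim_config` object.
#' @return A list of class `synthetic_registry` with elements
#'   \describe{
#'     \item{cases}{data.frame of case records: `race`, `age_group`,
#'       `age_group_index`, `era`, `dx_year`, `followup_years`,
#'       `outcome` (one of `cancer_death`, `other_death`,
#'       `alive_at_cutoff`).}
#'     \item{population}{data.frame of person-years per race x age band
#'       x calendar year.}
#'     \item{truth}{the [truth_table()] of the configuration.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_registry <- function(cfg) {
  validate_sim_config(cfg)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }

  k <- cfg$window_years
  tr <- truth_params(cfg)
  races <- c("white", "black")
  years_by_era <- lapply(seq_len(nrow(cfg$eras)),
                         function(e) seq(cfg$eras$start[e], cfg$eras$end[e]))

  pop <- list()
  stratum <- list()   # per-stratum case metadata, expanded at the end
  times <- list()
  outc <- list()
  idx <- 0L
  for (e in seq_len(nrow(cfg$eras))) {
    era_lab <- cfg$eras$label[e]
    for (a in seq_along(cfg$age_groups)) {
      row <- tr[tr$era == era_lab & tr$age_group_index == a - 1L, ]
      for (r in seq_along(races)) {
        race <- races[r]
        rate <- if (race == "white") row$incidence_white else row$incidence_black
        p_k <- if (race == "white") row$death_prob_white else row$death_prob_black
        lam_c <- if (p_k >= 1) Inf else -log(1 - p_k) / k
        lam_o <- cfg$other_cause_hazard[a]
        py <- cfg$person_years[race, a]
        for (yr in years_by_era[[e]]) {
          idx <- idx + 1L
          pop[[idx]] <- list(race = race, age_group = cfg$age_groups[a],
                             age_group_index = a - 1L, era = era_lab,
                             year = yr, person_years = py)
          set.seed(stratum_seed(cfg$seed, r - 1L, a - 1L, yr))
          n <- stats::rpois(1L, py * rate / 1e5)
          if (n == 0L) next
          t_cancer <- if (is.finite(lam_c) && lam_c > 0)
            stats::rexp(n, lam_c) else rep(Inf, n)
          t_other <- if (lam_o > 0) stats::rexp(n, lam_o) else rep(Inf, n)
          t_admin <- cfg$followup_cutoff_year - yr + 1
          stratum[[idx]] <- list(race = race, age_group = cfg$age_groups[a],
                                 age_group_index = a - 1L, era = era_lab,
                                 dx_year = yr, n = n)
          times[[idx]] <- pmin(t_cancer, t_other, t_admin)
          outc[[idx]] <- ifelse(t_cancer <= t_other & t_cancer <= t_admin,
                                "cancer_death",
                                ifelse(t_other <= t_admin, "other_death",
                                       "alive_at_cutoff"))
        }
      }
    }
  }
  filled <- !vapply(stratum, is.null, logical(1))
  stratum <- stratum[filled]
  n_per <- vapply(stratum, `[[`, integer(1), "n")
  rep_field <- function(fld, mode) {
    rep(vapply(stratum, `[[`, vector(mode, 1L), fld), times = n_per)
  }
  cases <- data.frame(
    race = rep_field("race", "character"),
    age_group = rep_field("age_group", "character"),
    age_group_index = rep_field("age_group_index", "integer"),
    era = rep_field("era", "character"),
    dx_year = rep_field("dx_year", "integer"),
    followup_years = unlist(times[filled], use.names = FALSE),
    outcome = unlist(outc[filled], use.names = FALSE),
    stringsAsFactors = FALSE)
  population <- data.frame(
    race = vapply(pop, `[[`, character(1), "race"),
    age_group = vapply(pop, `[[`, character(1), "age_group"),
    age_group_index = vapply(pop, `[[`, integer(1), "age_group_index"),
    era = vapply(pop, `[[`, character(1), "era"),
    year = vapply(pop, `[[`, numeric(1), "year"),
    person_years = vapply(pop, `[[`, numeric(1), "person_years"),
    stringsAsFactors = FALSE)
  population$year <- as.integer(population$year)
  structure(list(cases = cases, population = population,
                 truth = truth_table(cfg), config = cfg),
            class = "synthetic_registry")
}

#' @export
print.synthetic_registry <- function(x, ...) {
  cat(sprintf("Synthetic registry: %d cases, %d population strata, %d eras\n",
              nrow(x$cases), nrow(x$population), nrow(x$config$eras)))
  invisible(x)
}

# Weighted least-squares line through (x, y), by the closed-form normal
# equations for a straight line; equal weights by default.
ls_line <- function(x, y, w = rep(1, length(x))) {
  xb <- sum(w * x) / sum(w); yb <- sum(w * y) / sum(w)
  slope <- sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb)^2)
  c(intercept = yb - slope * xb, slope = slope)
}

#' Analytic inverse-variance weights for the true ratio table
#'
#' Approximates, per age band x era stratum, the large-sample variance
#' of the estimated Black/White ratio under the generating model, and
#' returns its reciprocal. Incidence ratios use the Poisson relative
#' variance `1/E[D_B] + 1/E[D_W]` with expected counts from the
#' configured person-years and rates; death-probability ratios use the
#' binomial relative variance `(1-p)/(p E[D])` per race (ignoring the
#' modest inflation from other-cause censoring); the fatal ratio sums
#' both. Only relative weights across strata matter for the weighted
#' linear projection, so overall scale is immaterial.
#'
#' @param cfg A `sim_config`.
#' @param metric One of `"incidence"`, `"death_prob"`, `"fatal"`.
#' @return Numeric weights aligned with the rows of [truth_table()].
#' @export
truth_ratio_weights <- function(cfg,
                                metric = c("incidence", "death_prob", "fatal")) {
  metric <- match.arg(metric)
  tt <- truth_table(cfg)
  n_years <- (cfg$eras$end - cfg$eras$start + 1)[match(tt$era, cfg$eras$label)]
  a <- tt$age_group_index + 1L
  ed_w <- cfg$person_years["white", a] * n_years * tt$incidence_white / 1e5
  ed_b <- cfg$person_years["black", a] * n_years * tt$incidence_black / 1e5
  relvar_inc <- 1 / ed_b + 1 / ed_w
  relvar_p <- (1 - tt$death_prob_black) / (tt$death_prob_black * ed_b) +
    (1 - tt$death_prob_white) / (tt$death_prob_white * ed_w)
  rr <- switch(metric, incidence = tt$rr_incidence,
               death_prob = tt$rr_death_prob, fatal = tt$rr_fatal)
  relvar <- switch(metric, incidence = relvar_inc, death_prob = relvar_p,
                   fatal = relvar_inc + relvar_p)
  1 / (rr^2 * relvar)
}

#' Generating trend coefficients of the ground truth
#'
#' The simulator generates Black/White ratios that are log-linear in the
#' age-band index k, while the trend module fits straight lines on the
#' natural ratio scale. For recovery studies to compare like with like,
#' this function returns, per era, both the generating log-scale
#' coefficients and the best linear-in-ratio approximation: the
#' least-squares straight line through the exact true ratios at
#' k = 0, ..., K-1. It also reports the coefficients of the two-era
#' interaction parameterisation (reference era = first configured era):
#' intercept and age slope of the reference era's linear approximation,
#' and the between-era differences in intercept (`era_shift`) and slope
#' (`age_era_interaction`).
#'
#' When the downstream fit is inverse-variance weighted, its estimand
#' is the weighted projection of the true ratio curve onto a straight
#' line, not the equal-weight one; supplying per-stratum `weights`
#' yields that target so recovery studies compare the weighted fit with
#' the matching weighted linear summary of the truth.
#'
#' @param truth A [truth_table()] data.frame (or a `synthetic_registry`).
#' @param metric One of `"incidence"`, `"death_prob"`, `"fatal"`.
#' @param weights Optional positive weights aligned with the rows of
#'   `truth` (one per age band x era); equal weights when `NULL`.
#' @return A list with components `per_era` (data.frame: era,
#'   log_intercept, log_slope, lin_intercept, lin_slope) and
#'   `coefficients` (named vector: intercept, age_slope, era_shift,
#'   age_era_interaction; the last two are `NA` for single-era
#'   configurations).
#' @export
truth_trend_coefficients <- function(truth,
                                     metric = c("incidence", "death_prob", "fatal"),
                                     weights = NULL) {
  metric <- match.arg(metric)
  if (inherits(truth, "synthetic_registry")) truth <- truth$truth
  if (is.null(weights)) weights <- rep(1, nrow(truth))
  if (length(weights) != nrow(truth) || any(weights <= 0))
    stop("truth_trend_coefficients: weights must be positive, one per truth row")
  col <- switch(metric, incidence = "rr_incidence",
                death_prob = "rr_death_prob", fatal = "rr_fatal")
  eras <- unique(truth$era)
  per_era <- do.call(rbind, lapply(eras, function(e) {
    sel <- truth$era == e
    sub <- truth[sel, ]
    w <- weights[sel]
    o <- order(sub$age_group_index)
    sub <- sub[o, ]; w <- w[o]
    k <- sub$age_group_index
    r <- sub[[col]]
    logfit <- ls_line(k, log(r))  # exact when the truth is log-linear
    linfit <- ls_line(k, r, w)
    data.frame(era = e,
               log_intercept = unname(logfit["intercept"]),
               log_slope = unname(logfit["slope"]),
               lin_intercept = unname(linfit["intercept"]),
               lin_slope = unname(linfit["slope"]),
               stringsAsFactors = FALSE)
  }))
  coefs <- c(intercept = per_era$lin_intercept[1],
             age_slope = per_era$lin_slope[1],
             era_shift = if (nrow(per_era) > 1)
               per_era$lin_intercept[2] - per_era$lin_intercept[1] else NA_real_,
             age_era_interaction = if (nrow(per_era) > 1)
               per_era$lin_slope[2] - per_era$lin_slope[1] else NA_real_)
  list(per_era = per_era, coefficients = coefs)
}
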