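#' Default 5-year age bands
#'
#' The default analytic age range is 45-84 years in eight 5-year bands.
#' Age groups are indexed 0..7 throughout the package, with 45-49 the
#' reference band (index 0).
#'
#' @return Character vector of age-band labels.
#' @export
default_age_groups <- function() {
  c("45-49", "50-54", "55-59", "60-64", "65-69", "70-74", "75-79", "80-84")
}

#' Default calendar eras
#'
#' Two diagnosis-year periods bracketing the dissemination of PSA
#' screening: a pre-PSA era (1980-1989) and a PSA era (2000-2009). The
#' intervening dissemination decade is deliberately omitted so that each
#' era reflects relatively stable diagnostic practice. The first row is
#' the reference era in trend fits.
#'
#' @return A data.frame with columns `label`, `start`, `end`.
#' @export
default_eras <- function() {
  data.frame(label = c("pre_psa", "psa"),
             start = c(1980L, 2000L),
             end   = c(1989L, 2009L),
             stringsAsFactors = FALSE)
}

#' Simulation configuration for the synthetic registry
#'
#' Builds and validates the parameter set governing the synthetic
#' SEER-like registry. The simulator draws Poisson case counts per
#' race x age-band x calendar-year stratum from supplied person-years
#' and incidence rates, then assigns each case a latent cancer-death
#' time and other-cause death time with administrative censoring.
#'
#' Black/White disparities are encoded as log-linear ratio trends over
#' the age-band index k: the Black/White incidence ratio is
#' `rr_incidence_intercept * exp(rr_incidence_slope * k)` and the ratio
#' of window death probabilities is
#' `rr_death_intercept * exp(rr_death_slope * k)`. Era multipliers scale
#' the White baselines identically for both races, so the generating
#' ratio structure is shared across eras (true era shift and
#' age-by-era interaction of the ratios are zero).
#'
#' Defaults emulate a SEER-9-scale registry: annual person-years per
#' age band of 6e5 (White) and 8e4 (Black), White incidence rising from
#' 10 to 650 per 100,000 across the bands in the earlier era, a 10-year
#' cancer-death probability rising from 0.25 to 0.46, an incidence
#' ratio declining from about 2.2 at ages 45-49, and a roughly constant
#' death-probability ratio near 1.5.
#'
#' @param age_groups Character vector of ordered 5-year band labels
#'   (>= 2 bands).
#' @param eras data.frame with columns `label`, `start`, `end`;
#'   non-overlapping diagnosis-year periods. First row is the reference.
#' @param person_years Named numeric `c(white=, black=)`: annual
#'   person-years per age band, or a races x age-bands matrix (rownames
#'   `white`, `black`) for band-specific denominators.
#' @param white_incidence White incidence per 100,000 person-years, one
#'   value per age band (era 1 baseline).
#' @param rr_incidence_intercept,rr_incidence_slope Parameters of the
#'   log-linear Black/White incidence ratio over the age index.
#' @param white_death_prob Probability of cancer death within
#'   `window_years` of diagnosis for White cases, per age band (era 1
#'   baseline).
#' @param rr_death_intercept,rr_death_slope Parameters of the log-linear
#'   Black/White ratio of window death probabilities.
#' @param era_incidence_multiplier,era_death_prob_multiplier One
#'   positive multiplier per era applied to the White baselines (both
#'   races inherit it, preserving the ratios). Defaults emulate higher
#'   incidence and lower fatality in the screening era.
#' @param other_cause_hazard Annual hazard of death from other causes,
#'   per age band.
#' @param followup_cutoff_year Administrative censoring: follow-up is
#'   truncated at the end of this calendar year.
#' @param window_years Window k (years) defining fatal cancer; 10 by
#'   default, 17 for the sensitivity analysis.
#' @param seed Integer root seed; per-stratum sub-streams are derived
#'   deterministically from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(age_groups = default_age_groups(),
                       eras = default_eras(),
                       person_years = c(white = 6e5, black = 8e4),
                       white_incidence = c(10, 40, 100, 200, 350, 500, 600, 650),
                       rr_incidence_intercept = 2.2,
                       rr_incidence_slope = -0.06,
                       white_death_prob = c(0.25, 0.28, 0.31, 0.34, 0.37, 0.40, 0.43, 0.46),
                       rr_death_intercept = 1.49,
                       rr_death_slope = -0.008,
                       era_incidence_multiplier = NULL,
                       era_death_prob_multiplier = NULL,
                       other_cause_hazard = c(0.010, 0.014, 0.020, 0.028, 0.040, 0.055, 0.075, 0.100),
                       followup_cutoff_year = 2017L,
                       window_years = 10L,
                       seed = 1L) {
  n_age <- length(age_groups)
  n_era <- nrow(eras)
  if (is.null(era_incidence_multiplier))
    era_incidence_multiplier <- if (n_era == 2) c(1, 1.6) else rep(1, n_era)
  if (is.null(era_death_prob_multiplier))
    era_death_prob_multiplier <- if (n_era == 2) c(1, 0.5) else rep(1, n_era)

  if (is.matrix(person_years)) {
    py <- person_years
  } else {
    py <- matrix(rep(as.numeric(person_years), each = n_age),
                 nrow = 2, ncol = n_age, byrow = TRUE,
                 dimnames = list(names(person_years), age_groups))
  }
  rownames(py) <- tolower(rownames(py))

  cfg <- structure(list(
    age_groups = as.character(age_groups),
    eras = eras,
    person_years = py,
    white_incidence = as.numeric(white_incidence),
    rr_incidence_intercept = rr_incidence_intercept,
    rr_incidence_slope = rr_incidence_slope,
    white_death_prob = as.numeric(white_death_prob),
    rr_death_intercept = rr_death_intercept,
    rr_death_slope = rr_death_slope,
    era_incidence_multiplier = as.numeric(era_incidence_multiplier),
    era_death_prob_multiplier = as.numeric(era_death_prob_multiplier),
    other_cause_hazard = as.numeric(other_cause_hazard),
    followup_cutoff_year = as.integer(followup_cutoff_year),
    window_years = as.integer(window_years),
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks structural invariants (>= 2 age bands, non-overlapping eras,
#' non-negative rates and hazards, probabilities in [0, 1]) and, most
#' importantly, that the implied Black death probability
#' `white_death_prob * ratio * era multiplier` does not exceed 1 in any
#' stratum: such a configuration is rejected with an error naming the
#' offending stratum rather than silently clipped.
#'
#' @param cfg A `sim_config` object.
#' @return `cfg`, invisibly, if valid; otherwise an error.
#' @export
validate_sim_config <- function(cfg) {
  n_age <- length(cfg$age_groups)
  if (n_age < 2L) stop("sim_config: need at least 2 age groups")
  eras <- cfg$eras
  if (!all(c("label", "start", "end") %in% names(eras)))
    stop("sim_config: eras must have columns label, start, end")
  if (anyDuplicated(eras$label)) stop("sim_config: duplicate era labels")
  if (any(eras$end < eras$start)) stop("sim_config: era end before start")
  if (nrow(eras) > 1L) {
    o <- order(eras$start)
    if (any(eras$start[o][-1] <= eras$end[o][-nrow(eras)]))
      stop("sim_config: eras overlap")
  }
  if (!all(rownames(cfg$person_years) %in% c("white", "black")) ||
      nrow(cfg$person_years) != 2L)
    stop("sim_config: person_years must cover races 'white' and 'black'")
  if (ncol(cfg$person_years) != n_age)
    stop("sim_config: person_years must have one column per age group")
  if (any(cfg$person_years <= 0)) stop("sim_config: person-years must be positive")
  for (fld in c("white_incidence", "white_death_prob", "other_cause_hazard")) {
    v <- cfg[[fld]]
    if (length(v) != n_age)
      stop("sim_config: ", fld, " must have one value per age group")
    if (any(!is.finite(v)) || any(v < 0))
      stop("sim_config: ", fld, " must be finite and non-negative")
  }
  if (any(cfg$white_death_prob > 1))
    stop("sim_config: white_death_prob must lie in [0, 1]")
  if (length(cfg$era_incidence_multiplier) != nrow(eras) ||
      length(cfg$era_death_prob_multiplier) != nrow(eras))
    stop("sim_config: era multipliers must have one value per era")
  if (any(cfg$era_incidence_multiplier < 0) || any(cfg$era_death_prob_multiplier < 0))
    stop("sim_config: era multipliers must be non-negative")
  if (cfg$window_years < 1L) stop("sim_config: window_years must be >= 1")
  if (any(cfg$rr_incidence_intercept <= 0) || any(cfg$rr_death_intercept <= 0))
    stop("sim_config: ratio intercepts must be positive")

  # implied Black death probability must stay within [0, 1] in every stratum
  k <- seq_len(n_age) - 1L
  rr_p <- cfg$rr_death_intercept * exp(cfg$rr_death_slope * k)
  for (e in seq_len(nrow(eras))) {
    p_b <- cfg$white_death_prob * cfg$era_death_prob_multiplier[e] * rr_p
    bad <- which(p_b > 1)
    if (length(bad)) {
      stop(sprintf(
        "sim_config: implied Black death probability %.3f exceeds 1 in stratum (era '%s', age group '%s')",
        p_b[bad[1]], eras$label[e], cfg$age_groups[bad[1]]))
    }
    p_w <- cfg$white_death_prob * cfg$era_death_prob_multiplier[e]
    badw <- which(p_w > 1)
    if (length(badw)) {
      stop(sprintf(
        "sim_config: implied White death probability %.3f exceeds 1 in stratum (era '%s', age group '%s')",
        p_w[badw[1]], eras$label[e], cfg$age_groups[badw[1]]))
    }
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic registry configuration\n")
  cat("  age groups : ", paste(x$age_groups, collapse = ", "), "\n", sep = "")
  cat("  eras       : ",
      paste(sprintf("%s (%d-%d)", x$eras$label, x$eras$start, x$eras$end),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  window     : %d years; follow-up cutoff %d\n",
              x$window_years, x$followup_cutoff_year))
  cat(sprintf("  incidence ratio: %.3g * exp(%.3g k); death-prob ratio: %.3g * exp(%.3g k)\n",
              x$rr_incidence_intercept, x$rr_incidence_slope,
              x$rr_death_intercept, x$rr_death_slope))
  cat(sprintf("  seed       : %d\n", x$seed))
  invisible(x)
}
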