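# Fatal-incidence composite and Black/White rate ratios with
# delta-method uncertainty.

#' Fatal-cancer incidence
#'
#' Composes an incidence estimate and a net-survival estimate for the
#' same stratum into the incidence of fatal cancer, `F = I * (1 - S)`:
#' the rate of diagnoses that lead to cancer-specific death within the
#' survival window. The variance is first-order delta-method with I and
#' S treated as independent (they come from different data dimensions:
#' Poisson counts vs conditional follow-up):
#' `Var(F) = (1 - S)^2 Var(I) + I^2 Var(S)`.
#'
#' @param inc One row (or aligned rows) of incidence estimates with
#'   columns `rate`, `variance`, and stratum keys `race`,
#'   `age_group_index`, `era`.
#' @param surv Matching net-survival estimates with columns `survival`,
#'   `variance` and the same stratum keys.
#' @return data.frame with stratum keys and columns `value` (F, same
#'   scale as the incidence rate), `variance`, `incidence`,
#'   `incidence_variance`, `survival`, `survival_variance`.
#' @export
fatal_incidence <- function(inc, surv) {
  keys <- c("race", "age_group_index", "era")
  if (all(keys %in% names(inc)) && all(keys %in% names(surv))) {
    m <- merge(inc, surv, by = keys, suffixes = c("_inc", "_surv"))
    if (nrow(m) != nrow(inc) || nrow(m) != nrow(surv))
      stop("fatal_incidence: stratum keys of incidence and survival tables do not match")
    inc_rate <- m$rate; inc_var <- m$variance_inc
    s <- m$survival; s_var <- m$variance_surv
    out <- m[keys]
  } else {
    if (nrow(inc) != nrow(surv))
      stop("fatal_incidence: inputs must align row-wise when stratum keys are absent")
    inc_rate <- inc$rate; inc_var <- inc$variance
    s <- surv$survival; s_var <- surv$variance
    out <- data.frame(row = seq_len(nrow(inc)))
  }
  out$value <- inc_rate * (1 - s)
  out$variance <- (1 - s)^2 * inc_var + inc_rate^2 * s_var
  out$incidence <- inc_rate
  out$incidence_variance <- inc_var
  out$survival <- s
  out$survival_variance <- s_var
  out
}

#' Black/White rate ratio with log-scale delta-method uncertainty
#'
#' Forms the ratio of two positive stratum estimates (Black numerator,
#' White denominator) with a standard error on the log scale by the
#' delta method under independence of the race groups:
#' `log_se^2 = Var_B / value_B^2 + Var_W / value_W^2`. For a Poisson
#' incidence rate this reduces to `1/D_B + 1/D_W`. The 95% CI is
#' log-normal: `rr * exp(-+ 1.96 log_se)`. Non-positive inputs are
#' degenerate: the ratio is undefined on the log scale and the row is
#' returned as missing (`NA`) with `degenerate = TRUE`.
#'
#' @param value_black,variance_black Numerator estimate(s) and
#'   variance(s).
#' @param value_white,variance_white Denominator estimate(s) and
#'   variance(s).
#' @param conf_level Confidence level for the log-normal CI.
#' @return data.frame with columns `rr`, `log_se`, `ci_low`, `ci_high`,
#'   `degenerate`. Vectorised.
#' @export
rate_ratio <- function(value_black, variance_black,
                       value_white, variance_white,
                       conf_level = 0.95) {
  bad <- !is.finite(value_black) | !is.finite(value_white) |
    value_black <= 0 | value_white <= 0
  rr <- ifelse(bad, NA_real_, value_black / value_white)
  log_se <- ifelse(bad, NA_real_,
                   sqrt(variance_black / value_black^2 +
                        variance_white / value_white^2))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(rr = rr, log_se = log_se,
             ci_low = rr * exp(-z * log_se),
             ci_high = rr * exp(z * log_se),
             degenerate = bad)
}

#' Decompose disparities into incidence, fatality and fatal incidence
#'
#' Builds the full ratio table of the analysis: for every age band x era
#' stratum, the Black/White ratio of (i) the incidence rate, (ii) the
#' window death probability `1 - S`, and (iii) the fatal-cancer
#' incidence `I * (1 - S)`, each with log-scale delta-method SE and
#' log-normal CI. The fatal point estimate factorises exactly:
#' `rr_fatal = rr_incidence * rr_death_prob` in every cell. Strata that
#' are degenerate (zero cases, or zero death probability) are emitted
#' with `NA` ratios and `degenerate = TRUE`, and excluded from trend
#' fitting downstream.
#'
#' @param incidence Per-stratum incidence estimates
#'   ([estimate_incidence()] layout) covering both races.
#' @param survival Per-stratum net-survival estimates
#'   ([estimate_survival()] layout) covering both races.
#' @param conf_level Confidence level for the CIs.
#' @return A tidy data.frame: `metric` (`incidence`, `death_prob`,
#'   `fatal`), `era`, `age_group_index`, `age_group` (when available),
#'   `rr`, `log_se`, `ci_low`, `ci_high`, `black_value`, `white_value`,
#'   `degenerate`.
#' @export
decompose <- function(incidence, survival, conf_level = 0.95) {
  keys <- c("age_group_index", "era")
  surv <- death_probability(survival)
  fat <- fatal_incidence(incidence, survival)

  value_cols <- function(df, value, variance) {
    b <- df[df$race == "black", c(keys, value, variance)]
    w <- df[df$race == "white", c(keys, value, variance)]
    names(b)[3:4] <- c("vb", "varb"); names(w)[3:4] <- c("vw", "varw")
    merge(b, w, by = keys)
  }
  pieces <- list(
    incidence = value_cols(incidence, "rate", "variance"),
    death_prob = value_cols(surv, "death_prob", "death_prob_variance"),
    fatal = value_cols(fat, "value", "variance"))

  out <- do.call(rbind, lapply(names(pieces), function(metric) {
    m <- pieces[[metric]]
    rr <- rate_ratio(m$vb, m$varb, m$vw, m$varw, conf_level = conf_level)
    cbind(data.frame(metric = metric, stringsAsFactors = FALSE),
          m[keys],
          data.frame(rr, black_value = m$vb, white_value = m$vw))
  }))
  if ("age_group" %in% names(incidence)) {
    map <- unique(incidence[c("age_group_index", "age_group")])
    out <- merge(out, map, by = "age_group_index", sort = FALSE)
  }
  out <- out[order(match(out$metric, names(pieces)), out$era,
                   out$age_group_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}
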