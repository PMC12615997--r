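# Per-stratum incidence and net cause-specific survival estimators.

#' Incidence rate with Poisson variance
#'
#' Computes the incidence rate per `scale` person-years, `rate = scale *
#' D / PY`, with Poisson variance `scale^2 * D / PY^2`. Vectorised.
#' Zero-case inputs yield a zero rate and zero variance and are flagged
#' degenerate: they carry no information on the log scale and are
#' excluded from ratio construction downstream.
#'
#' @param cases Non-negative integer case count(s) D.
#' @param person_years Positive person-year denominator(s) PY.
#' @param scale Rate scale, 100,000 by default.
#' @return data.frame with columns `cases`, `person_years`, `rate`,
#'   `variance`, `degenerate`.
#' @export
incidence_rate <- function(cases, person_years, scale = 1e5) {
  if (any(!is.finite(person_years)) || any(person_years <= 0))
    stop("incidence_rate: person_years must be positive and finite")
  if (any(!is.finite(cases)) || any(cases < 0))
    stop("incidence_rate: cases must be non-negative")
  data.frame(cases = cases,
             person_years = person_years,
             rate = scale * cases / person_years,
             variance = scale^2 * cases / person_years^2,
             degenerate = cases == 0)
}

#' Era-level incidence estimates per stratum
#'
#' Counts diagnoses per race x age band x era and sums person-years over
#' the era's calendar years before forming the rate, so each stratum's
#' estimate is a single Poisson rate over the pooled era denominator.
#'
#' @param cases Case-listing data.frame (`race`, `age_group_index`,
#'   `era`, ...), e.g. `simulate_registry()$cases`.
#' @param population Person-year table (`race`, `age_group_index`,
#'   `era`, `year`, `person_years`).
#' @param scale Rate scale, 100,000 by default.
#' @return data.frame keyed by `race`, `age_group_index`, `age_group`,
#'   `era` with the [incidence_rate()] columns.
#' @export
estimate_incidence <- function(cases, population, scale = 1e5) {
  py <- stats::aggregate(person_years ~ race + age_group_index + era,
                         data = population, FUN = sum)
  if (nrow(cases)) {
    cnt <- stats::aggregate(list(cases = rep(1L, nrow(cases))),
                            by = cases[c("race", "age_group_index", "era")],
                            FUN = sum)
    out <- merge(py, cnt, by = c("race", "age_group_index", "era"),
                 all.x = TRUE)
  } else {
    out <- py
    out$cases <- 0L
  }
  out$cases[is.na(out$cases)] <- 0L
  est <- incidence_rate(out$cases, out$person_years, scale = scale)
  out <- cbind(out[c("race", "age_group_index", "era")], est)
  if ("age_group" %in% names(population)) {
    map <- unique(population[c("age_group_index", "age_group")])
    out <- merge(out, map, by = "age_group_index", sort = FALSE)
  }
  out[order(out$era, out$race, out$age_group_index), , drop = FALSE]
}

# Product-limit (Kaplan-Meier) estimate of net cause-specific survival at
# `window` years, with Greenwood variance. `status` is 1 for a cancer
# death, 0 for a censoring (other-cause death or administratively alive).
# Ties between deaths and censorings at the same time are resolved with
# deaths first, the standard product-limit convention: a subject censored
# at t remains in the risk set for deaths at t.
km_at <- function(time, status, window) {
  stopifnot(length(time) == length(status), length(time) > 0L)
  if (any(time < 0)) stop("net_survival: negative follow-up time")
  ut <- sort(unique(time))
  f <- match(time, ut)
  d_all <- as.numeric(tabulate(f[status == 1], nbins = length(ut)))
  n_all <- as.numeric(tabulate(f, nbins = length(ut)))
  at_risk <- rev(cumsum(rev(n_all)))  # subjects with time >= ut[i]
  ev <- which(d_all > 0 & ut <= window)
  flagged <- FALSE
  if (length(ev) == 0L) {
    s <- 1; v <- 0; d_tot <- 0L
  } else {
    n_risk <- at_risk[ev]
    d <- d_all[ev]
    s_path <- cumprod(1 - d / n_risk)
    s <- s_path[length(s_path)]
    if (s > 0) {
      v <- s^2 * sum(d / (n_risk * (n_risk - d)))
    } else {
      v <- 0  # Greenwood sum diverges at S = 0; variance reported as 0
      flagged <- TRUE
    }
    d_tot <- as.integer(sum(d))
  }
  if (max(time) < window && s > 0) flagged <- TRUE  # risk set exhausted early
  list(survival = s, variance = v, n_initial = length(time),
       n_events = d_tot, flagged = flagged)
}

# Actuarial (life-table) analogue on one-year intervals (i-1, i], with
# half-interval withdrawal adjustment: effective denominator
# n_eff = n_start - w/2. Matches registry software that tabulates
# survival on annual intervals.
actuarial_at <- function(time, status, window) {
  stopifnot(length(time) > 0L)
  if (any(time < 0)) stop("net_survival: negative follow-up time")
  n_at_risk <- length(time)
  s <- 1; gw <- 0; d_tot <- 0L; flagged <- FALSE
  for (i in seq_len(window)) {
    if (n_at_risk <= 0) { flagged <- TRUE; break }
    in_int <- time > (i - 1) & time <= i
    d <- sum(in_int & status == 1)
    w <- sum(in_int & status == 0)
    n_eff <- n_at_risk - w / 2
    if (n_eff > 0 && d > 0) {
      if (d >= n_eff) { s <- 0; gw <- 0; d_tot <- d_tot + as.integer(d); break }
      s <- s * (1 - d / n_eff)
      gw <- gw + d / (n_eff * (n_eff - d))
    }
    d_tot <- d_tot + as.integer(d)
    n_at_risk <- n_at_risk - d - w
  }
  list(survival = s, variance = if (s > 0) s^2 * gw else 0,
       n_initial = length(time), n_events = d_tot,
       flagged = flagged || (max(time) < window && s > 0))
}

#' Net cause-specific survival at the window
#'
#' Estimates the probability of surviving the cancer of interest to
#' `window_years` after diagnosis, treating deaths from the cancer as
#' events and everything else — other-cause deaths and administrative
#' follow-up ends — as censorings (the registry definition of net
#' cause-specific survival). The default estimator is the continuous-time
#' product-limit (Kaplan-Meier) with Greenwood variance; an annual-
#' interval actuarial option is provided for users matching life-table
#' registry output. Ties between deaths and censorings resolve deaths
#' first. If the risk set is exhausted before the window with survival
#' still positive, the last value is carried forward and the estimate is
#' flagged.
#'
#' @param records data.frame of one stratum's case records with columns
#'   `followup_years` and `outcome` (`cancer_death` is the event; any
#'   other value censors).
#' @param window_years Window k in years.
#' @param method `"km"` (product-limit, default) or `"actuarial"`.
#' @return data.frame with columns `window_years`, `survival`,
#'   `variance`, `n_initial`, `n_events`, `flagged`.
#' @export
net_survival <- function(records, window_years,
                         method = c("km", "actuarial")) {
  method <- match.arg(method)
  if (!nrow(records)) stop("net_survival: empty stratum")
  time <- records$followup_years
  status <- as.integer(records$outcome == "cancer_death")
  res <- if (method == "km") km_at(time, status, window_years)
         else actuarial_at(time, status, window_years)
  data.frame(window_years = window_years, survival = res$survival,
             variance = res$variance, n_initial = res$n_initial,
             n_events = res$n_events, flagged = res$flagged)
}

#' Per-stratum net survival estimates
#'
#' Applies [net_survival()] to every race x age band x era stratum of a
#' case listing. Era membership follows the year of diagnosis; follow-up
#' may extend past the era's end.
#'
#' @param cases Case-listing data.frame (`race`, `age_group_index`,
#'   `era`, `followup_years`, `outcome`).
#' @param window_years Window k in years.
#' @param method Passed to [net_survival()].
#' @return data.frame keyed by `race`, `age_group_index`, `era` with the
#'   [net_survival()] columns.
#' @export
estimate_survival <- function(cases, window_years,
                              method = c("km", "actuarial")) {
  method <- match.arg(method)
  fn <- if (method == "km") km_at else actuarial_at
  status <- as.integer(cases$outcome == "cancer_death")
  grp <- interaction(cases$era, cases$race, cases$age_group_index, drop = TRUE)
  idx <- split(seq_len(nrow(cases)), grp)
  res <- do.call(rbind, lapply(idx, function(i) {
    r <- fn(cases$followup_years[i], status[i], window_years)
    data.frame(race = cases$race[i[1]],
               age_group_index = cases$age_group_index[i[1]],
               era = cases$era[i[1]],
               window_years = window_years, survival = r$survival,
               variance = r$variance, n_initial = r$n_initial,
               n_events = r$n_events, flagged = r$flagged,
               stringsAsFactors = FALSE)
  }))
  res <- res[order(res$era, res$race, res$age_group_index), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Window death probability from a survival estimate
#'
#' The probability of cancer death within the window is the complement
#' of net survival, `p = 1 - S`; being a linear transform, its variance
#' equals the Greenwood variance of S unchanged.
#'
#' @param surv data.frame from [net_survival()] or [estimate_survival()]
#'   (must contain `survival` and `variance`).
#' @return The input with columns `death_prob = 1 - survival` and
#'   `death_prob_variance = variance` appended.
#' @export
death_probability <- function(surv) {
  surv$death_prob <- 1 - surv$survival
  surv$death_prob_variance <- surv$variance
  surv
}
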