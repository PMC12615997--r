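# CSV schemas, pipeline configuration and the end-to-end runner.
#
# Canonical schemas (all plain UTF-8 CSV, one row per record/stratum):
#   case listing : race, age_group, age_group_index, dx_year,
#                  followup_years, outcome
#   population   : race, age_group, age_group_index, year, person_years
#   aggregate    : race, age_group, age_group_index, era, cases,
#                  person_years, survival, survival_se
# SEER*Stat exports can be adapted to these by renaming headers; no
# attempt is made to parse SEER*Stat session files.

races_allowed <- c("white", "black")
outcomes_allowed <- c("cancer_death", "other_death", "alive_at_cutoff")

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
}

check_numeric <- function(df, cols, path) {
  for (col in cols) {
    v <- df[[col]]
    if (is.character(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop(sprintf("%s: non-numeric value '%s' in column '%s' (row %d)",
                     path, v[bad[1]], col, bad[1]))
      df[[col]] <- vn
    }
    bad <- which(is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("%s: missing value in column '%s' (row %d)",
                   path, col, bad[1]))
  }
  df
}

check_levels <- function(df, col, allowed, path) {
  bad <- which(!df[[col]] %in% allowed)
  if (length(bad))
    stop(sprintf("%s: unknown %s '%s' (row %d); allowed: %s",
                 path, col, df[[col]][bad[1]], bad[1],
                 paste(allowed, collapse = ", ")))
}

#' Read a case listing CSV
#'
#' Columns: `race` (white/black), `age_group`, `age_group_index`,
#' `dx_year`, `followup_years`, `outcome` (cancer_death / other_death /
#' alive_at_cutoff). Unknown race or outcome labels and non-numeric
#' fields are rejected with the offending row number.
#'
#' @param path Path to the CSV file.
#' @return A validated data.frame of case records.
#' @export
read_case_listing <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("race", "age_group_index", "dx_year",
                      "followup_years", "outcome"), path)
  df$race <- tolower(df$race)
  check_levels(df, "race", races_allowed, path)
  check_levels(df, "outcome", outcomes_allowed, path)
  df <- check_numeric(df, c("age_group_index", "dx_year", "followup_years"), path)
  bad <- which(df$followup_years < 0)
  if (length(bad))
    stop(sprintf("%s: negative followup_years (row %d)", path, bad[1]))
  df
}

#' Read a population person-year CSV
#'
#' Columns: `race`, `age_group`, `age_group_index`, `year`,
#' `person_years`. One row per race x age band x calendar year;
#' duplicate strata are rejected.
#'
#' @param path Path to the CSV file.
#' @return A validated data.frame of person-years.
#' @export
read_population <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("race", "age_group_index", "year", "person_years"), path)
  df$race <- tolower(df$race)
  check_levels(df, "race", races_allowed, path)
  df <- check_numeric(df, c("age_group_index", "year", "person_years"), path)
  if (any(df$person_years <= 0))
    stop(sprintf("%s: non-positive person_years (row %d)",
                 path, which(df$person_years <= 0)[1]))
  key <- paste(df$race, df$age_group_index, df$year)
  if (anyDuplicated(key))
    stop(sprintf("%s: duplicate stratum (row %d)", path, anyDuplicated(key)))
  df
}

#' Read an aggregate estimates CSV
#'
#' For the aggregate mode of the pipeline: pre-computed per-stratum
#' incidence inputs (case counts and person-years) and window net
#' survival with its standard error, one row per race x age band x era.
#' This is the shape of a registry-software extraction (e.g. SEER*Stat
#' incidence and survival sessions) after renaming headers.
#'
#' @param path Path to the CSV file.
#' @return A list with `incidence` and `survival` data.frames in the
#'   layouts of [estimate_incidence()] and [estimate_survival()]
#'   (survival `variance` is `survival_se^2`).
#' @examples
#' path <- system.file("extdata", "synthetic_aggregate.csv",
#'                     package = "fatalinc")
#' tabs <- read_aggregate(path)
#' head(tabs$incidence)
#' @export
read_aggregate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("race", "age_group_index", "era", "cases",
                      "person_years", "survival", "survival_se"), path)
  df$race <- tolower(df$race)
  check_levels(df, "race", races_allowed, path)
  df <- check_numeric(df, c("age_group_index", "cases", "person_years",
                            "survival", "survival_se"), path)
  bad <- which(df$survival < 0 | df$survival > 1)
  if (length(bad))
    stop(sprintf("%s: survival outside [0, 1] (row %d)", path, bad[1]))
  key <- paste(df$race, df$age_group_index, df$era)
  if (anyDuplicated(key))
    stop(sprintf("%s: duplicate stratum (row %d)", path, anyDuplicated(key)))

  keys <- intersect(c("race", "age_group_index", "age_group", "era"), names(df))
  inc <- cbind(df[keys], incidence_rate(df$cases, df$person_years))
  surv <- df[keys]
  surv$survival <- df$survival
  surv$variance <- df$survival_se^2
  surv$n_initial <- df$cases
  surv$n_events <- NA_integer_
  surv$flagged <- FALSE
  list(incidence = inc, survival = surv)
}

#' Write a synthetic registry to CSV
#'
#' Writes `cases.csv`, `population.csv` and `truth.csv` plus a YAML echo
#' of the generating configuration into a directory.
#'
#' @param registry A `synthetic_registry` from [simulate_registry()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_registry <- function(registry, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("cases.csv", "population.csv", "truth.csv",
                            "sim_config.yaml"))
  utils::write.csv(registry$cases, paths[1], row.names = FALSE)
  utils::write.csv(registry$population, paths[2], row.names = FALSE)
  utils::write.csv(registry$truth, paths[3], row.names = FALSE)
  writeLines(yaml::as.yaml(sim_config_as_list(registry$config)), paths[4])
  invisible(paths)
}

sim_config_as_list <- function(cfg) {
  out <- unclass(cfg)
  out$eras <- lapply(seq_len(nrow(cfg$eras)), function(i)
    list(label = cfg$eras$label[i], start = cfg$eras$start[i],
         end = cfg$eras$end[i]))
  out$person_years <- list(white = unname(cfg$person_years["white", ]),
                           black = unname(cfg$person_years["black", ]))
  out
}

#' Assign diagnosis years to eras
#'
#' @param years Integer vector of diagnosis years.
#' @param eras Era definition data.frame (`label`, `start`, `end`).
#' @return Character vector of era labels, `NA` for years outside every
#'   era.
#' @export
assign_era <- function(years, eras) {
  out <- rep(NA_character_, length(years))
  for (i in seq_len(nrow(eras))) {
    sel <- years >= eras$start[i] & years <= eras$end[i]
    out[sel] <- eras$label[i]
  }
  out
}

#' Pipeline configuration
#'
#' Assembles and validates the options for [run_pipeline()].
#'
#' @param mode `"synthetic"` (simulate a registry), `"micro_csv"` (read
#'   a case listing + population CSV) or `"aggregate_csv"` (read
#'   pre-computed per-stratum estimates).
#' @param window_years Fatal-cancer window in years (10 by default; 17
#'   for the sensitivity analysis).
#' @param eras Era definitions, [default_eras()] by default.
#' @param case_listing,population,aggregate File paths for the CSV
#'   modes.
#' @param seed Root seed (synthetic mode).
#' @param out_dir Output directory; `NULL` to return results without
#'   writing files.
#' @param survival_method `"km"` or `"actuarial"`.
#' @param weights,response Passed to [fit_trend()].
#' @param conf_level Confidence level used throughout.
#' @param sim Optional `sim_config` overriding the default simulator
#'   settings (synthetic mode); its eras, window and seed take
#'   precedence.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "micro_csv", "aggregate_csv"),
                            window_years = 10L,
                            eras = default_eras(),
                            case_listing = NULL, population = NULL,
                            aggregate = NULL,
                            seed = 1L, out_dir = NULL,
                            survival_method = c("km", "actuarial"),
                            weights = c("invvar", "equal"),
                            response = c("ratio", "log"),
                            conf_level = 0.95,
                            sim = NULL) {
  mode <- match.arg(mode)
  survival_method <- match.arg(survival_method)
  weights <- match.arg(weights)
  response <- match.arg(response)
  if (window_years < 1L) stop("pipeline_config: window_years must be >= 1")
  if (mode == "micro_csv") {
    for (p in c(case_listing, population))
      if (is.null(p) || !file.exists(p))
        stop("pipeline_config: micro_csv mode needs existing case_listing and population files")
  }
  if (mode == "aggregate_csv") {
    if (is.null(aggregate) || !file.exists(aggregate))
      stop("pipeline_config: aggregate_csv mode needs an existing aggregate file")
  }
  if (mode == "synthetic" && is.null(sim)) {
    sim <- sim_config(eras = eras, window_years = window_years,
                      seed = as.integer(seed))
  } else if (!is.null(sim)) {
    sim$eras <- eras
    sim$window_years <- as.integer(window_years)
    sim$seed <- as.integer(seed)
    validate_sim_config(sim)
  }
  structure(list(mode = mode, window_years = as.integer(window_years),
                 eras = eras, case_listing = case_listing,
                 population = population, aggregate = aggregate,
                 seed = as.integer(seed), out_dir = out_dir,
                 survival_method = survival_method, weights = weights,
                 response = response, conf_level = conf_level, sim = sim),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised top-level keys mirror the arguments of
#' [pipeline_config()]; `eras` is a list of `{label, start, end}`
#' mappings. Unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @param ... Overrides applied on top of the file (e.g. from CLI
#'   flags).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  known <- c("mode", "window_years", "eras", "case_listing", "population",
             "aggregate", "seed", "out_dir", "survival_method", "weights",
             "response", "conf_level")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop(path, ": unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$eras)) {
    raw$eras <- do.call(rbind, lapply(raw$eras, function(e)
      data.frame(label = e$label, start = as.integer(e$start),
                 end = as.integer(e$end), stringsAsFactors = FALSE)))
  }
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  do.call(pipeline_config, raw)
}

#' Run the full disparity-decomposition pipeline
#'
#' Executes, in order: input acquisition (simulate, or read CSVs),
#' per-stratum incidence and net-survival estimation, decomposition into
#' Black/White rate ratios of incidence, window death probability and
#' fatal incidence, and one weighted age-trend fit per metric. With an
#' output directory set, writes `incidence.csv`, `survival.csv`,
#' `ratios.csv`, `trend_<metric>.csv`, a human-readable `pipeline.log`,
#' a machine-readable `summary.json` and a YAML echo of the
#' configuration. Degenerate or flagged strata are reported in the log,
#' never silently dropped from the tables.
#'
#' @param config A `pipeline_config`.
#' @return A list of class `pipeline_result`: `incidence`, `survival`,
#'   `ratios`, `trends` (named list of `trend_model`s), `registry`
#'   (synthetic mode only), `log` (character vector), `config`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("run_pipeline: config must be a pipeline_config")
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))

  registry <- NULL
  if (config$mode == "synthetic") {
    say("stage simulate: synthetic registry, seed %d", config$seed)
    registry <- simulate_registry(config$sim)
    cases <- registry$cases
    population <- registry$population
    say("stage simulate: %d cases in %d population strata",
        nrow(cases), nrow(population))
  } else if (config$mode == "micro_csv") {
    say("stage read: case listing %s", config$case_listing)
    cases <- read_case_listing(config$case_listing)
    population <- read_population(config$population)
    cases$era <- assign_era(cases$dx_year, config$eras)
    population$era <- assign_era(population$year, config$eras)
    n_out <- sum(is.na(cases$era))
    if (n_out) say("stage read: dropped %d case(s) outside configured eras", n_out)
    cases <- cases[!is.na(cases$era), , drop = FALSE]
    population <- population[!is.na(population$era), , drop = FALSE]
    if (!nrow(population)) stop("run_pipeline: no population rows inside the configured eras")
  }

  if (config$mode == "aggregate_csv") {
    say("stage read: aggregate estimates %s", config$aggregate)
    agg <- read_aggregate(config$aggregate)
    incidence <- agg$incidence
    survival <- agg$survival
  } else {
    say("stage estimate: incidence and %d-year net survival (%s)",
        config$window_years, config$survival_method)
    incidence <- estimate_incidence(cases, population)
    survival <- estimate_survival(cases, config$window_years,
                                  method = config$survival_method)
    for (i in which(survival$flagged))
      say("stage estimate: flagged survival stratum (%s, age index %d, era %s)",
          survival$race[i], survival$age_group_index[i], survival$era[i])
  }

  say("stage decompose: %d incidence strata", nrow(incidence))
  ratios <- decompose(incidence, survival, conf_level = config$conf_level)
  for (i in which(ratios$degenerate))
    say("stage decompose: degenerate stratum excluded from trends (metric %s, age index %d, era %s)",
        ratios$metric[i], ratios$age_group_index[i], ratios$era[i])

  trends <- list()
  for (metric in c("incidence", "death_prob", "fatal")) {
    sub <- ratios[ratios$metric == metric, , drop = FALSE]
    trends[[metric]] <- fit_trend(sub, weights = config$weights,
                                  response = config$response,
                                  ref_era = config$eras$label[1],
                                  conf_level = config$conf_level)
    say("stage trend [%s]: age slope %.4f (p = %.3g) on %d observations",
        metric, trends[[metric]]$coefficients[["age_slope"]],
        trends[[metric]]$p[["age_slope"]], trends[[metric]]$n_obs)
  }

  result <- structure(list(incidence = incidence, survival = survival,
                           ratios = ratios, trends = trends,
                           registry = registry, log = log, config = config),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$incidence, file.path(dir, "incidence.csv"),
                   row.names = FALSE)
  utils::write.csv(result$survival, file.path(dir, "survival.csv"),
                   row.names = FALSE)
  utils::write.csv(result$ratios, file.path(dir, "ratios.csv"),
                   row.names = FALSE)
  for (metric in names(result$trends))
    utils::write.csv(trend_coef_table(result$trends[[metric]]),
                     file.path(dir, paste0("trend_", metric, ".csv")),
                     row.names = FALSE)
  writeLines(result$log, file.path(dir, "pipeline.log"))
  cfg <- result$config
  echo <- list(mode = cfg$mode, window_years = cfg$window_years,
               seed = cfg$seed, survival_method = cfg$survival_method,
               weights = cfg$weights, response = cfg$response,
               conf_level = cfg$conf_level,
               eras = lapply(seq_len(nrow(cfg$eras)), function(i)
                 list(label = cfg$eras$label[i], start = cfg$eras$start[i],
                      end = cfg$eras$end[i])))
  writeLines(yaml::as.yaml(echo), file.path(dir, "config_echo.yaml"))
  summary <- list(
    n_strata = nrow(result$incidence),
    n_degenerate = sum(result$ratios$degenerate),
    trends = lapply(result$trends, function(m)
      as.list(stats::setNames(unname(m$coefficients), names(m$coefficients)))))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Disparity decomposition pipeline (%s mode, %d-year window)\n",
              x$config$mode, x$config$window_years))
  cat(sprintf("  %d ratio rows (%d degenerate)\n",
              nrow(x$ratios), sum(x$ratios$degenerate)))
  for (m in names(x$trends)) {
    b <- x$trends[[m]]$coefficients
    cat(sprintf("  %-10s intercept %.3f, age slope %.3f\n",
                m, b[["intercept"]], b[["age_slope"]]))
  }
  invisible(x)
}
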