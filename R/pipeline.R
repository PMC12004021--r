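#' Pipeline configuration
#'
#' Bundles every choice of a cohort analysis run: the lifecycle preset, the
#' enrichment toggles (the nested iteration sequence structured-only, then
#' +diagnoses, then +text), an optional WHR availability scenario, category
#' cutoffs, the coefficient file and the evaluation grid.
#'
#' @param lifecycle A [lifecycle_policy()] or preset name.
#' @param use_diagnoses,use_text Enrichment toggles.
#' @param whr_scenario Optional [whr_scenario()]; `NULL` leaves the cohort
#'   without simulated WHR data.
#' @param coefficients A [clivd_coefficients()] object or a path to a
#'   coefficient file; `NULL` loads the packaged synthetic stand-in.
#' @param cutoffs Named numeric `c(low, high)` category cutoffs; `NULL` takes
#'   them from the coefficient file.
#' @param grid_years Years of the annual evaluation grid (evaluated each
#'   December 31).
#' @param age_window Inclusive eligible age window.
#' @param abstainer_mode See [screen_exclusions()].
#' @param diabetes_missing_as_false See [derive_diabetes()].
#' @param seed Optional integer seed for the scenario simulation.
#' @return A `clivd_pipeline_config` list.
#' @export
pipeline_config <- function(lifecycle = lifecycle_policy("infinite"),
                            use_diagnoses = TRUE, use_text = TRUE,
                            whr_scenario = NULL,
                            coefficients = NULL,
                            cutoffs = NULL,
                            grid_years = 2014:2021,
                            age_window = c(40, 70),
                            abstainer_mode = "text_confirmed",
                            diabetes_missing_as_false = TRUE,
                            seed = NULL) {
  if (is.character(lifecycle)) lifecycle <- lifecycle_policy(lifecycle)
  if (is.null(coefficients)) {
    coefficients <- clivd_coefficients()
  } else if (is.character(coefficients)) {
    coefficients <- clivd_coefficients(coefficients)
  }
  if (!is.null(whr_scenario) && !inherits(whr_scenario, "clivd_whr_scenario")) {
    abort("`whr_scenario` must be a whr_scenario() or NULL")
  }
  cutoffs <- cutoffs %||% coefficients$cutoffs
  structure(
    list(lifecycle = lifecycle, use_diagnoses = use_diagnoses,
         use_text = use_text, whr_scenario = whr_scenario,
         coefficients = coefficients, cutoffs = cutoffs,
         grid_years = grid_years, age_window = age_window,
         abstainer_mode = abstainer_mode,
         diabetes_missing_as_false = diabetes_missing_as_false,
         seed = seed),
    class = "clivd_pipeline_config"
  )
}

#' @export
print.clivd_pipeline_config <- function(x, ...) {
  cat("<clivd_pipeline_config>\n")
  cat(sprintf("  lifecycle: %s | diagnoses: %s | text: %s | WHR scenario: %s\n",
              x$lifecycle$preset, x$use_diagnoses, x$use_text,
              if (is.null(x$whr_scenario)) "none" else x$whr_scenario$mode))
  cat(sprintf("  grid: %d-%d | cutoffs %.0f%%/%.0f%% | ages %d-%d\n",
              min(x$grid_years), max(x$grid_years),
              100 * x$cutoffs[1], 100 * x$cutoffs[2],
              x$age_window[1], x$age_window[2]))
  invisible(x)
}

#' Per-patient, per-grid-date risk intervals for a cohort
#'
#' The pipeline core: applies the WHR scenario (if any), builds the enriched
#' evidence table, screens exclusions at every grid date, resolves the
#' min/max input pair, scores both ends with the CLivD risk function and
#' categorizes the interval. Patients failing exclusion screening at a date
#' keep their row with `eligible = FALSE` and no risk values.
#'
#' @param cohort A [clivd_cohort()].
#' @param config A [pipeline_config()].
#' @param dates Optional explicit query dates; default December 31 of each
#'   `config$grid_years`.
#' @return Tibble with one row per patient and date: demographics, exclusion
#'   reasons, `eligible`, `variant`, `risk_min`, `risk_max`, `width`,
#'   `category`, `substituted`.
#' @export
cohort_risk <- function(cohort, config = pipeline_config(), dates = NULL) {
  dates <- as.Date(dates %||% sprintf("%d-12-31", sort(config$grid_years)))
  if (!is.null(config$whr_scenario)) {
    if (!is.null(config$seed)) set.seed(config$seed)
    cohort <- apply_whr_scenario(cohort, config$whr_scenario, config$age_window)
  }
  evidence <- build_evidence(cohort, config$use_diagnoses, config$use_text)
  scheme <- if (!is.null(config$whr_scenario)) {
    whr_bin_scheme(config$whr_scenario$scheme)
  }

  excl <- purrr::map(dates, function(d) {
    screen_exclusions(cohort, d, config$lifecycle, config$age_window,
                      config$abstainer_mode) |>
      mutate(query_date = d)
  }) |> bind_rows()

  states <- states_at(cohort, dates, config$lifecycle, evidence,
                      under_18 = "drop")
  elig_keys <- excl |> filter(!.data$excluded) |>
    select("patient_id", "query_date")
  states_elig <- states |>
    inner_join(elig_keys, by = c("patient_id", "query_date"))

  out <- excl |>
    left_join(cohort$patients |> select("patient_id", "sex"), by = "patient_id") |>
    select("patient_id", "query_date", "sex", "age", "age_out_of_range",
           "liver_disease_dx", "viral_hepatitis_dx",
           "alcohol_abstainer_prior_use", "excluded")

  if (nrow(states_elig) > 0) {
    scored <- resolve_inputs(states_elig,
                             diabetes_missing_as_false = config$diabetes_missing_as_false,
                             whr_scheme = scheme, check_age = TRUE,
                             age_window = config$age_window) |>
      risk_interval(config$coefficients) |>
      mutate(category = categorize_risk(.data$risk_min, .data$risk_max,
                                        config$cutoffs)) |>
      select("patient_id", "query_date", "variant", "risk_min", "risk_max",
             "width", "category", "substituted")
    out <- left_join(out, scored, by = c("patient_id", "query_date"))
  } else {
    out <- out |>
      mutate(variant = NA_character_, risk_min = NA_real_, risk_max = NA_real_,
             width = NA_real_,
             category = factor(NA, levels = levels(categorize_risk(0, 0))),
             substituted = list(NULL))
  }
  out |>
    mutate(eligible = !.data$excluded) |>
    arrange(.data$patient_id, .data$query_date)
}

#' Mean risk difference by year
#'
#' Averages the risk-interval width (maximum risk minus minimum risk) over the
#' patients eligible at each grid year's evaluation date. Smaller means imply
#' more precise risk assessment. Years with no eligible patients report a
#' missing (not zero) mean.
#'
#' @inheritParams cohort_risk
#' @param risk Optionally, a precomputed [cohort_risk()] table.
#' @return Tibble `year`, `mean_width`, `n_eligible`.
#' @export
mean_risk_difference_by_year <- function(cohort, config = pipeline_config(),
                                         risk = NULL) {
  risk <- risk %||% cohort_risk(cohort, config)
  risk |>
    mutate(year = as.integer(format(.data$query_date, "%Y"))) |>
    group_by(.data$year) |>
    summarise(
      mean_width = if (any(.data$eligible)) mean(.data$width[.data$eligible]) else NA_real_,
      n_eligible = sum(.data$eligible),
      .groups = "drop"
    )
}

#' Most precise categorization over a patient's history
#'
#' For each patient, selects the grid date with the narrowest risk interval
#' (ties broken by the latest date) and returns that date's interval and
#' category. Patients never eligible on the grid are marked excluded and get
#' no category.
#'
#' @inheritParams mean_risk_difference_by_year
#' @return Tibble `patient_id`, `eligible_ever`, `query_date`, `risk_min`,
#'   `risk_max`, `width`, `category`.
#' @export
best_category_over_history <- function(cohort, config = pipeline_config(),
                                       risk = NULL) {
  risk <- risk %||% cohort_risk(cohort, config)
  best <- risk |>
    filter(.data$eligible) |>
    arrange(.data$patient_id, .data$width, desc(.data$query_date)) |>
    distinct(.data$patient_id, .keep_all = TRUE) |>
    select("patient_id", "query_date", "risk_min", "risk_max", "width",
           "category")
  cohort$patients |>
    select("patient_id") |>
    left_join(best, by = "patient_id") |>
    mutate(eligible_ever = !is.na(.data$width), .after = "patient_id")
}

#' Categorize a cohort
#'
#' Runs the full pipeline: per-year mean risk differences, per-patient best
#' (most precise) categorization, category counts and exclusion-reason
#' tabulation, under one named configuration.
#'
#' @inheritParams cohort_risk
#' @return A `clivd_report` object; see [tidy.clivd_report()],
#'   [glance.clivd_report()] and [autoplot.clivd_report()].
#' @export
categorize_cohort <- function(cohort, config = pipeline_config()) {
  risk <- cohort_risk(cohort, config)
  best <- best_category_over_history(cohort, config, risk = risk)
  by_year <- mean_risk_difference_by_year(cohort, config, risk = risk)

  eligible <- best |> filter(.data$eligible_ever)
  counts <- eligible |>
    count(.data$category, .drop = FALSE) |>
    rename(n = "n")

  reasons <- risk |>
    group_by(.data$patient_id) |>
    summarise(ever_eligible = any(.data$eligible),
              age_out_of_range = all(.data$age_out_of_range),
              liver_disease_dx = any(.data$liver_disease_dx),
              viral_hepatitis_dx = any(.data$viral_hepatitis_dx),
              alcohol_abstainer_prior_use = any(.data$alcohol_abstainer_prior_use),
              .groups = "drop") |>
    filter(!.data$ever_eligible)
  reason_counts <- tibble(
    reason = c("age_out_of_range", "liver_disease_dx", "viral_hepatitis_dx",
               "alcohol_abstainer_prior_use"),
    n = c(sum(reasons$age_out_of_range), sum(reasons$liver_disease_dx),
          sum(reasons$viral_hepatitis_dx),
          sum(reasons$alcohol_abstainer_prior_use))
  )

  structure(
    list(category_counts = counts, by_year = by_year, best = best,
         n_patients = nrow(cohort$patients),
         n_eligible = nrow(eligible),
         n_excluded = nrow(cohort$patients) - nrow(eligible),
         exclusion_reasons = reason_counts,
         config = config),
    class = "clivd_report"
  )
}

#' @export
print.clivd_report <- function(x, ...) {
  cat(sprintf("<clivd_report> %d patients: %d eligible, %d excluded\n",
              x$n_patients, x$n_eligible, x$n_excluded))
  cc <- x$category_counts
  cat("  categories:",
      paste(sprintf("%s %d", cc$category, cc$n), collapse = ", "), "\n")
  yr <- x$by_year
  ok <- !is.na(yr$mean_width)
  if (any(ok)) {
    cat(sprintf("  mean risk difference: %.3f (%d) -> %.3f (%d)\n",
                yr$mean_width[ok][1], yr$year[ok][1],
                tail(yr$mean_width[ok], 1), tail(yr$year[ok], 1)))
  }
  invisible(x)
}

#' Tidy a cohort report
#'
#' @param x A `clivd_report`.
#' @param ... Unused.
#' @return The per-category counts as a tibble with proportions among
#'   eligible patients.
#' @export
tidy.clivd_report <- function(x, ...) {
  x$category_counts |>
    mutate(prop_eligible = if (x$n_eligible > 0) .data$n / x$n_eligible else NA_real_)
}

#' One-row summary of a cohort report
#'
#' @inheritParams tidy.clivd_report
#' @return One-row tibble: cohort sizes, per-category counts, the share of
#'   eligible patients placed in a definite (non-not-specified) category, and
#'   the first/last-year mean risk difference.
#' @export
glance.clivd_report <- function(x, ...) {
  cc <- setNames(x$category_counts$n, paste0("n_", x$category_counts$category))
  yr <- x$by_year[!is.na(x$by_year$mean_width), ]
  tibble(
    n_patients = x$n_patients, n_eligible = x$n_eligible,
    n_excluded = x$n_excluded, !!!cc,
    prop_categorized = if (x$n_eligible > 0) {
      1 - cc[["n_not_specified"]] / x$n_eligible
    } else NA_real_,
    first_year_mean_width = if (nrow(yr)) yr$mean_width[1] else NA_real_,
    last_year_mean_width = if (nrow(yr)) tail(yr$mean_width, 1) else NA_real_
  )
}

#' Run the pipeline from a configuration file
#'
#' Reads a YAML run configuration (optionally with a `generator` block for a
#' synthetic cohort or a `cohort` path to an event file), executes
#' [categorize_cohort()], and writes machine-readable outputs to `out_dir`:
#' `by_year.csv` (per-year mean risk difference), `categories.csv`,
#' `best_categories.csv` (per-patient) and `report.yaml` (summary, config
#' echo, stage timings).
#'
#' @param config_path Path to a YAML run configuration.
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @return The `clivd_report`, invisibly.
#' @export
run_pipeline <- function(config_path, out_dir = NULL) {
  t0 <- Sys.time()
  raw <- yaml::read_yaml(config_path)
  if (!is.null(raw$coefficients) && !file.exists(raw$coefficients)) {
    abort(c(sprintf("coefficient file not found: %s", raw$coefficients),
            i = "set `coefficients:` to a readable coefficient YAML, or omit it to use the packaged synthetic stand-in"))
  }
  scenario <- NULL
  if (!is.null(raw$whr_scenario)) {
    scenario <- do.call(whr_scenario, raw$whr_scenario)
  }
  config <- pipeline_config(
    lifecycle = raw$lifecycle %||% "infinite",
    use_diagnoses = raw$use_diagnoses %||% TRUE,
    use_text = raw$use_text %||% TRUE,
    whr_scenario = scenario,
    coefficients = raw$coefficients,
    grid_years = raw$grid_years %||% 2014:2021,
    abstainer_mode = raw$abstainer_mode %||% "text_confirmed",
    seed = raw$seed
  )
  if (!is.null(raw$generator)) {
    gen_args <- raw$generator
    gen_args$seed <- gen_args$seed %||% raw$seed
    cohort <- generate_cohort(do.call(cohort_config, gen_args))
  } else if (!is.null(raw$cohort)) {
    cohort <- read_events(raw$cohort)
  } else {
    abort("run configuration needs a `generator` block or a `cohort` file path")
  }
  t1 <- Sys.time()
  report <- categorize_cohort(cohort, config)
  t2 <- Sys.time()

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(report$by_year, file.path(out_dir, "by_year.csv"))
    readr::write_csv(tidy(report), file.path(out_dir, "categories.csv"))
    readr::write_csv(
      report$best |> mutate(category = as.character(.data$category)),
      file.path(out_dir, "best_categories.csv"))
    yaml::write_yaml(
      list(
        summary = as.list(glance(report)),
        exclusion_reasons = setNames(as.list(report$exclusion_reasons$n),
                                     report$exclusion_reasons$reason),
        config = list(lifecycle = config$lifecycle$preset,
                      use_diagnoses = config$use_diagnoses,
                      use_text = config$use_text,
                      whr_scenario = if (is.null(config$whr_scenario)) "none" else
                        unclass(config$whr_scenario),
                      cutoffs = as.list(config$cutoffs),
                      grid_years = range(config$grid_years),
                      seed = config$seed),
        timings_seconds = list(
          load_or_generate = as.numeric(difftime(t1, t0, units = "secs")),
          analysis = as.numeric(difftime(t2, t1, units = "secs")))
      ),
      file.path(out_dir, "report.yaml"))
  }
  invisible(report)
}
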