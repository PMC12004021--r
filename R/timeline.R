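#' Parameter lifecycle policy
#'
#' A lifecycle policy defines how long a dated record stays valid for risk
#' calculation. Two presets mirror common practice: `"one_year"` (measurements
#' valid for 365 days after the measurement date) and `"infinite"`
#' (measurements stay valid until superseded by the next measurement of the
#' same parameter). Diagnoses have infinite validity under both presets and
#' accumulate over time.
#'
#' @param preset `"infinite"` (default) or `"one_year"`, or `NULL` when
#'   supplying `measurement_lifetime` directly.
#' @param measurement_lifetime Validity window in days after a measurement
#'   (`Inf` for last-observation-carried-forward).
#' @param diagnosis_lifetime Validity window in days for diagnoses; `Inf` by
#'   default.
#' @param overrides Named numeric vector of per-parameter lifetime overrides
#'   in days, e.g. `c(ggt = 180)`.
#' @param lookback Days a record may also apply *before* its date (backward
#'   validity). Default 0: validity is forward-only, so future measurements
#'   never inform past risk.
#' @return A `clivd_lifecycle` list.
#' @export
#' @examples
#' lifecycle_policy("one_year")
#' lifecycle_policy(measurement_lifetime = 730, overrides = c(ggt = 180))
lifecycle_policy <- function(preset = c("infinite", "one_year"),
                             measurement_lifetime = NULL,
                             diagnosis_lifetime = Inf,
                             overrides = NULL,
                             lookback = 0) {
  if (is.null(measurement_lifetime)) {
    preset <- match.arg(preset)
    measurement_lifetime <- if (preset == "one_year") 365 else Inf
  } else {
    preset <- "custom"
  }
  if (measurement_lifetime <= 0 || diagnosis_lifetime <= 0) {
    abort("lifetimes must be strictly positive")
  }
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      abort("`overrides` must be a named vector of parameter lifetimes")
    }
    if (any(overrides <= 0)) abort("lifetimes must be strictly positive")
  }
  if (lookback < 0) abort("`lookback` must be non-negative")
  structure(
    list(preset = preset,
         measurement_lifetime = measurement_lifetime,
         diagnosis_lifetime = diagnosis_lifetime,
         overrides = overrides %||% numeric(),
         lookback = lookback),
    class = "clivd_lifecycle"
  )
}

#' @export
print.clivd_lifecycle <- function(x, ...) {
  cat(sprintf("<clivd_lifecycle> %s: measurements %s days, diagnoses %s days, lookback %g\n",
              x$preset, format(x$measurement_lifetime), format(x$diagnosis_lifetime),
              x$lookback))
  invisible(x)
}

.lifetime_for <- function(policy, parameter) {
  lt <- rep(policy$measurement_lifetime, length(parameter))
  if (length(policy$overrides)) {
    idx <- match(parameter, names(policy$overrides))
    lt[!is.na(idx)] <- policy$overrides[idx[!is.na(idx)]]
  }
  lt
}

# risk-model input parameters carried in a resolved state
.state_parameters <- c("smoking", "alcohol", "whr", "ggt",
                       "fasting_glucose", "diabetes_dx")

# structured measurement -> state parameter
.structured_param_map <- c(
  smoking_status = "smoking",
  alcohol_servings_per_week = "alcohol",
  whr = "whr",
  ggt = "ggt",
  fasting_glucose = "fasting_glucose"
)

# Build the internal evidence table: one row per piece of risk-model evidence
# with its interval value, source and lifecycle class. Structured measurements
# are always included; diagnosis- and text-derived evidence is added by the
# enrichment layer (see merge_evidence()).
.structured_evidence <- function(cohort) {
  e <- cohort$events |> mutate(.row = row_number())
  m <- e |>
    filter(.data$kind == "measurement",
           .data$parameter %in% names(.structured_param_map))
  tibble(
    patient_id = m$patient_id,
    source_date = m$date,
    parameter = unname(.structured_param_map[m$parameter]),
    vmin = m$value, vmax = m$value,
    source = as.character(ifelse(coalesce(m$source, "structured") == "simulated",
                                 "simulated", "structured")),
    lifecycle_class = "measurement",
    .row = m$.row
  )
}

.diabetes_dx_codes <- list(
  `ICD-10` = c("E10", "E11", "E12", "E13", "E14"),
  `ICPC-2` = c("T89", "T90")
)

.diabetes_dx_evidence <- function(cohort, diabetes_codes = .diabetes_dx_codes) {
  d <- cohort$events |> mutate(.row = row_number()) |>
    filter(.data$kind == "diagnosis")
  if (nrow(d) == 0) return(NULL)
  hit <- purrr::map_lgl(seq_len(nrow(d)), function(i) {
    pats <- diabetes_codes[[d$system[i]]]
    !is.null(pats) && any(code_matches(d$code[i], pats))
  })
  d <- d[hit, ]
  if (nrow(d) == 0) return(NULL)
  tibble(patient_id = d$patient_id, source_date = d$date,
         parameter = "diabetes_dx", vmin = 1, vmax = 1,
         source = "diagnosis", lifecycle_class = "diagnosis", .row = d$.row)
}

.source_rank <- c(structured = 1, simulated = 1, text = 2, diagnosis = 3)

# Resolve an evidence table at query dates: for each patient, date and
# parameter keep the best-precedence, most recent record whose validity
# window covers the date.
.resolve_evidence <- function(evidence, grid, policy) {
  if (is.null(evidence) || nrow(evidence) == 0) {
    joined <- grid[0, ]
    resolved <- tibble(patient_id = character(), query_date = as.Date(character()),
                       parameter = character(), vmin = numeric(), vmax = numeric(),
                       source = character(), source_date = as.Date(character()))
  } else {
    joined <- inner_join(grid, evidence, by = "patient_id",
                         relationship = "many-to-many")
    lt <- ifelse(joined$lifecycle_class == "diagnosis",
                 policy$diagnosis_lifetime,
                 .lifetime_for(policy, joined$parameter))
    delta <- as.numeric(joined$query_date - joined$source_date)
    valid <- (delta >= 0 & delta < lt) |
      (delta < 0 & -delta <= policy$lookback)
    resolved <- joined[valid, ] |>
      mutate(.rank = .source_rank[.data$source]) |>
      arrange(.data$patient_id, .data$query_date, .data$parameter,
              .data$.rank, desc(.data$source_date), desc(.data$.row)) |>
      distinct(.data$patient_id, .data$query_date, .data$parameter,
               .keep_all = TRUE) |>
      select("patient_id", "query_date", "parameter", "vmin", "vmax",
             "source", "source_date")
  }
  full <- tidyr::expand_grid(grid, parameter = .state_parameters) |>
    left_join(resolved, by = c("patient_id", "query_date", "parameter")) |>
    mutate(source = coalesce(.data$source, "missing"))
  full
}

#' Resolve the risk-model parameter state at a query date
#'
#' For every patient, determines which risk-model inputs are valid at `date`
#' under the lifecycle policy: the most recent record of each parameter whose
#' validity window covers the date. Diagnoses accumulate (every diagnosis
#' dated at or before the query date is active under the default infinite
#' diagnosis lifetime). Values are carried as `(vmin, vmax)` intervals so that
#' category-valued evidence (alcohol-use categories, binned waist-hip ratio)
#' and exact measurements share one representation; an exact measurement has
#' `vmin == vmax`.
#'
#' @param cohort A [clivd_cohort()].
#' @param date Query date (single `Date`).
#' @param policy A [lifecycle_policy()].
#' @param evidence Optional pre-built evidence table (from [merge_evidence()]
#'   with enrichment, or the structured-only default).
#' @param under_18 What to do with patients younger than 18 at `date`:
#'   `"error"` (default, the state is undefined for minors) or `"drop"`.
#' @return A tibble with one row per patient and parameter: `patient_id`,
#'   `query_date`, `sex`, `age`, `parameter`, `vmin`, `vmax`, `source`
#'   (`structured`, `simulated`, `text`, `diagnosis` or `missing`),
#'   `source_date`.
#' @export
state_at <- function(cohort, date, policy = lifecycle_policy(),
                     evidence = NULL, under_18 = c("error", "drop")) {
  .assert_date_scalar(date)
  under_18 <- match.arg(under_18)
  states_at(cohort, dates = date, policy = policy, evidence = evidence,
            under_18 = under_18)
}

# vectorized over query dates; shared by state_at() and annual_grid()
states_at <- function(cohort, dates, policy = lifecycle_policy(),
                      evidence = NULL, under_18 = c("error", "drop")) {
  under_18 <- match.arg(under_18)
  if (is.null(evidence)) {
    evidence <- bind_rows(.structured_evidence(cohort),
                          .diabetes_dx_evidence(cohort))
  }
  grid <- tidyr::expand_grid(
    cohort$patients |> select("patient_id", "sex", "birth_date"),
    query_date = as.Date(dates)
  ) |>
    mutate(age = age_at(.data$birth_date, .data$query_date))
  if (any(grid$age < 18)) {
    if (under_18 == "error") {
      abort("query date precedes a patient's 18th birthday; the parameter state is undefined for minors")
    }
    grid <- grid[grid$age >= 18, ]
  }
  .resolve_evidence(evidence, grid |> select(-"birth_date"), policy) |>
    select("patient_id", "query_date", "sex", "age", "parameter",
           "vmin", "vmax", "source", "source_date") |>
    arrange(.data$patient_id, .data$query_date, .data$parameter)
}

#' Annual evaluation grid of parameter states
#'
#' Resolves one parameter state per patient per year, evaluated at December 31
#' of each grid year (the yearly series evaluation date).
#'
#' @inheritParams state_at
#' @param years Integer vector of years (within 2000-2100).
#' @return A tibble as in [state_at()], one block per grid date.
#' @export
annual_grid <- function(cohort, years, policy = lifecycle_policy(),
                        evidence = NULL, under_18 = c("drop", "error")) {
  under_18 <- match.arg(under_18)
  if (length(years) == 0) {
    return(states_at(cohort, as.Date(character()), policy, evidence)[0, ])
  }
  if (any(years < 2000 | years > 2100)) abort("`years` must lie within 2000-2100")
  dates <- as.Date(sprintf("%d-12-31", sort(unique(years))))
  states_at(cohort, dates, policy, evidence, under_18 = under_18)
}

#' Active diagnoses at a query date
#'
#' All diagnosis events whose validity window covers the query date (infinite
#' by default, so diagnoses accumulate over the record history).
#'
#' @inheritParams state_at
#' @return Tibble `patient_id`, `date`, `system`, `code`.
#' @export
active_diagnoses <- function(cohort, date, policy = lifecycle_policy()) {
  .assert_date_scalar(date)
  d <- cohort$events |> filter(.data$kind == "diagnosis")
  delta <- as.numeric(date - d$date)
  keep <- (delta >= 0 & delta < policy$diagnosis_lifetime) |
    (delta < 0 & -delta <= policy$lookback)
  d[keep, c("patient_id", "date", "system", "code")]
}
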