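#' Waist-hip-ratio availability scenario
#'
#' Describes how simulated WHR data are injected into a cohort to study how
#' coverage of the model's key adiposity input narrows the risk interval.
#' Three modes: `document_coverage` (each event date independently carries a
#' WHR measurement with probability `coverage`; defaults 0.5% and 10% mirror
#' low and high structured-data availability), `self_report_exact` and
#' `self_report_categorical` (one self-reported WHR per patient at their first
#' eligible date). Values are drawn from sex-specific normal distributions
#' (male mean 0.96, female mean 0.84, variance 0.07 — representative of the
#' Finnish adult population). Note the stated dispersion is interpreted
#' literally as a *variance* (SD about 0.26), which is physiologically wide;
#' set `variance_is_sd = TRUE` to reinterpret it as an SD instead. Draws are
#' truncated to the physiological range (0.3, 2.0) unless `truncate = FALSE`.
#'
#' @param mode One of `"document_coverage"`, `"self_report_exact"`,
#'   `"self_report_categorical"`.
#' @param coverage Per-event-date probability of carrying a WHR measurement
#'   (document-coverage mode only).
#' @param scheme Category scheme applied downstream: `"exact"`, `"three_bin"`
#'   or `"five_bin"` (see [whr_bin_scheme()]).
#' @param male_mean,female_mean,variance Generator parameters.
#' @param variance_is_sd Interpret `variance` as a standard deviation.
#' @param truncate Truncate draws to (0.3, 2.0).
#' @return A `clivd_whr_scenario` list.
#' @export
whr_scenario <- function(mode = c("document_coverage", "self_report_exact",
                                  "self_report_categorical"),
                         coverage = 0.005,
                         scheme = c("exact", "three_bin", "five_bin"),
                         male_mean = 0.96, female_mean = 0.84,
                         variance = 0.07, variance_is_sd = FALSE,
                         truncate = TRUE) {
  mode <- match.arg(mode)
  scheme <- match.arg(scheme)
  if (coverage < 0 || coverage > 1) abort("`coverage` must be in [0, 1]")
  if (male_mean <= 0.5 || male_mean >= 1.5 || female_mean <= 0.5 || female_mean >= 1.5) {
    abort("means must lie in (0.5, 1.5)")
  }
  if (variance <= 0) abort("`variance` must be positive")
  structure(
    list(mode = mode, coverage = coverage, scheme = scheme,
         male_mean = male_mean, female_mean = female_mean,
         variance = variance, variance_is_sd = variance_is_sd,
         truncate = truncate),
    class = "clivd_whr_scenario"
  )
}

#' @export
print.clivd_whr_scenario <- function(x, ...) {
  cat(sprintf("<clivd_whr_scenario> %s", x$mode))
  if (x$mode == "document_coverage") cat(sprintf(" (coverage %.3g)", x$coverage))
  cat(sprintf(", scheme %s, N(%.2f/%.2f, %s %.3g)%s\n",
              x$scheme, x$male_mean, x$female_mean,
              if (x$variance_is_sd) "sd" else "var", x$variance,
              if (x$truncate) ", truncated (0.3, 2.0)" else ""))
  invisible(x)
}

#' Draw simulated waist-hip ratios
#'
#' Normal draws with the sex-specific scenario mean, truncated by rejection to
#' the physiological range (0.3, 2.0) when the scenario requests truncation.
#' Reproducible under R's RNG: call `set.seed()` before drawing.
#'
#' @param n Number of draws.
#' @param sex `"male"`/`"female"`, recycled to length `n`.
#' @param scenario A [whr_scenario()].
#' @return Numeric vector of length `n`.
#' @export
draw_whr <- function(n, sex, scenario = whr_scenario()) {
  sex <- rep_len(sex, n)
  if (any(!sex %in% .clivd_sexes)) abort("sex must be 'male' or 'female'")
  mu <- ifelse(sex == "male", scenario$male_mean, scenario$female_mean)
  sd <- if (scenario$variance_is_sd) scenario$variance else sqrt(scenario$variance)
  x <- rnorm(n, mu, sd)
  if (scenario$truncate) {
    bad <- which(x <= .clivd_whr_range[1] | x >= .clivd_whr_range[2])
    while (length(bad) > 0) {
      x[bad] <- rnorm(length(bad), mu[bad], sd)
      bad <- bad[x[bad] <= .clivd_whr_range[1] | x[bad] >= .clivd_whr_range[2]]
    }
  }
  x
}

#' Inject simulated WHR measurements into a cohort
#'
#' In `document_coverage` mode every distinct event date of every patient
#' independently receives a WHR measurement with probability
#' `scenario$coverage`; in the self-report modes each patient receives a
#' single WHR measurement at their first age-eligible event date. Added events
#' are tagged `source = "simulated"`; original events are untouched. Values
#' are rounded to 4 decimals so cohorts round-trip exactly through the event
#' file format.
#'
#' @param cohort A [clivd_cohort()].
#' @param scenario A [whr_scenario()].
#' @param age_window Eligible age window used by the self-report modes.
#' @return A new `clivd_cohort` with the simulated events appended.
#' @export
apply_whr_scenario <- function(cohort, scenario = whr_scenario(),
                               age_window = c(40, 70)) {
  ev_dates <- cohort$events |>
    distinct(.data$patient_id, .data$date) |>
    left_join(cohort$patients |> select("patient_id", "sex", "birth_date"),
              by = "patient_id")
  if (nrow(ev_dates) == 0) return(cohort)

  if (scenario$mode == "document_coverage") {
    pick <- ev_dates[rbinom(nrow(ev_dates), 1, scenario$coverage) == 1, ]
  } else {
    age <- age_at(ev_dates$birth_date, ev_dates$date)
    elig <- ev_dates[age >= age_window[1] & age <= age_window[2], ]
    pick <- elig |>
      arrange(.data$patient_id, .data$date) |>
      distinct(.data$patient_id, .keep_all = TRUE)
  }
  if (nrow(pick) == 0) return(cohort)
  new_events <- tibble(
    patient_id = pick$patient_id, date = pick$date, kind = "measurement",
    parameter = "whr",
    value = round(draw_whr(nrow(pick), pick$sex, scenario), 4),
    system = NA_character_, code = NA_character_, text = NA_character_,
    source = "simulated"
  )
  clivd_cohort(cohort$patients, bind_rows(cohort$events, new_events),
               validate = FALSE)
}

#' Waist-hip-ratio category scheme
#'
#' Bin edges for converting an exact WHR into a category interval used for
#' risk substitution (emulating a self-reported body-type question). The
#' default three-bin edges are (0.85, 1.00); the five-bin edges
#' (0.85, 0.93, 1.00, 1.10) refine the three-bin scheme — they contain the
#' three-bin edges, so every five-bin interval is nested inside a three-bin
#' interval, which is nested inside the full substitution default (0.7, 1.3).
#' Outer bins clamp to the (0.7, 1.3) substitution defaults; an observed value
#' outside its bin's clamped bounds widens the bound to enclose the value.
#'
#' @param name `"exact"`, `"three_bin"`, `"five_bin"`, or `"custom"` with
#'   `edges` supplied.
#' @param edges Strictly increasing bin edges inside (0.3, 2.0) for a custom
#'   scheme.
#' @return A `clivd_whr_scheme` list with `name`, `edges`, `lo`, `hi` (per-bin
#'   substitution bounds).
#' @export
whr_bin_scheme <- function(name = c("exact", "three_bin", "five_bin", "custom"),
                           edges = NULL) {
  name <- match.arg(name)
  edges <- switch(name,
    exact = numeric(),
    three_bin = c(0.85, 1.00),
    five_bin = c(0.85, 0.93, 1.00, 1.10),
    custom = edges
  )
  if (name == "custom") {
    if (is.null(edges) || any(diff(edges) <= 0)) {
      abort("custom scheme needs strictly increasing `edges`")
    }
    if (any(edges <= .clivd_whr_range[1] | edges >= .clivd_whr_range[2])) {
      abort("edges must lie inside (0.3, 2.0)")
    }
  }
  lo <- c(0.7, edges)
  hi <- c(edges, 1.3)
  structure(list(name = name, edges = edges, lo = lo, hi = hi),
            class = "clivd_whr_scheme")
}

#' Bin a waist-hip ratio into its category bounds
#'
#' Returns the enclosing bin's substitution bounds; the `"exact"` scheme
#' returns `(value, value)`. The returned interval always encloses the value.
#'
#' @param value Numeric WHR values in (0.3, 2.0).
#' @param scheme A [whr_bin_scheme()].
#' @return Tibble with columns `whr_min`, `whr_max`.
#' @export
#' @examples
#' bin_whr(0.96, whr_bin_scheme("three_bin"))  # middle bin (0.85, 1.00)
bin_whr <- function(value, scheme = whr_bin_scheme("exact")) {
  if (any(value <= .clivd_whr_range[1] | value >= .clivd_whr_range[2])) {
    abort("whr value outside the physiological range (0.3, 2.0)")
  }
  if (identical(scheme$name, "exact")) {
    return(tibble(whr_min = value, whr_max = value))
  }
  idx <- findInterval(value, scheme$edges) + 1L
  tibble(whr_min = pmin(scheme$lo[idx], value),
         whr_max = pmax(scheme$hi[idx], value))
}
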