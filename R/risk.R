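#' Substitution defaults for missing risk-model inputs
#'
#' The extreme values substituted for a missing input when computing the
#' minimum and maximum risk: waist-hip ratio (0.7, 1.3), smoking
#' (false, true), alcohol (0, 49 servings/week), diabetes (false, true).
#' A missing GGT does not get a value: it switches scoring to the non-GGT
#' model variant at both ends of the interval.
#'
#' @return Named list of `c(min, max)` pairs.
#' @export
clivd_defaults <- function() {
  list(whr = c(0.7, 1.3), smoking = c(0, 1), alcohol = c(0, 49),
       diabetes = c(0, 1))
}

.exclusion_liver <- c("K70", "K71", "K72", "K73", "K74", "K75", "K76", "K77",
                      "C22.0")
.exclusion_hepatitis <- "B18"
.exclusion_abstainer <- "F10.2X"

#' Screen risk-model exclusion criteria
#'
#' A patient is excluded from risk calculation at a query date when any of the
#' following hold: age outside the eligible window (40-70 by default); an
#' active chronic liver disease diagnosis (ICD-10 K70-K77 families or C22.0);
#' an active chronic viral hepatitis diagnosis (ICD-10 B18 family); or
#' current-alcohol-abstainer-with-prior-use evidence. Because the alcohol
#' dependence codes (F10.2x) double as heavy-use evidence for the alcohol
#' approximation, the abstainer flag is, by default, raised only when an
#' F10.2x code co-occurs with an abstinence text finding
#' (`abstainer_mode = "text_confirmed"`); `"code_only"` excludes on the code
#' alone and `"off"` disables the criterion.
#'
#' @inheritParams state_at
#' @param age_window Inclusive eligible age range, default `c(40, 70)`.
#' @param abstainer_mode `"text_confirmed"` (default), `"code_only"` or
#'   `"off"`.
#' @param keyword_table Keyword table used to find abstinence text findings
#'   when `abstainer_mode = "text_confirmed"`.
#' @return Tibble with one row per patient: `patient_id`, `age`, logical
#'   reason columns `age_out_of_range`, `liver_disease_dx`,
#'   `viral_hepatitis_dx`, `alcohol_abstainer_prior_use`, and `excluded`
#'   (true iff any reason is true).
#' @export
screen_exclusions <- function(cohort, date, policy = lifecycle_policy(),
                              age_window = c(40, 70),
                              abstainer_mode = c("text_confirmed", "code_only", "off"),
                              keyword_table = clivd_keywords()) {
  .assert_date_scalar(date)
  abstainer_mode <- match.arg(abstainer_mode)
  p <- cohort$patients
  age <- age_at(p$birth_date, date)

  dx <- active_diagnoses(cohort, date, policy)
  icd <- dx[dx$system == "ICD-10", ]
  liver_hit <- Reduce(`|`, lapply(.exclusion_liver,
                                  function(pat) code_matches(icd$code, pat)),
                      rep(FALSE, nrow(icd)))
  liver_ids <- unique(icd$patient_id[liver_hit])
  hep_ids <- unique(icd$patient_id[code_matches(icd$code, .exclusion_hepatitis)])
  f102_ids <- unique(icd$patient_id[code_matches(icd$code, .exclusion_abstainer)])

  abst_ids <- character()
  if (abstainer_mode == "code_only") {
    abst_ids <- f102_ids
  } else if (abstainer_mode == "text_confirmed" && length(f102_ids) > 0) {
    te <- cohort$events |>
      filter(.data$kind == "text", .data$date <= date,
             .data$patient_id %in% f102_ids)
    if (nrow(te) > 0) {
      f <- extract_text_findings(te$text, keyword_table)
      none_idx <- f$text_index[f$kind == "alcohol_category" & f$category == "none"]
      abst_ids <- unique(te$patient_id[none_idx])
    }
  }

  tibble(
    patient_id = p$patient_id,
    age = age,
    age_out_of_range = age < age_window[1] | age > age_window[2],
    liver_disease_dx = p$patient_id %in% liver_ids,
    viral_hepatitis_dx = p$patient_id %in% hep_ids,
    alcohol_abstainer_prior_use = p$patient_id %in% abst_ids
  ) |>
    mutate(excluded = .data$age_out_of_range | .data$liver_disease_dx |
             .data$viral_hepatitis_dx | .data$alcohol_abstainer_prior_use)
}

#' Derive diabetes status from diagnoses and fasting glucose
#'
#' Diabetes is true when an active diabetes diagnosis (ICD-10 E10-E14 families
#' or ICPC-2 T89/T90 by default) is present, or any valid fasting glucose is
#' at or above 7 mmol/L; false when a valid fasting glucose is below 7 with no
#' diagnosis. With neither source of evidence the status is interpreted as
#' "no diabetes" by default (`missing_as_false = TRUE`); set it to `FALSE` to
#' keep the status missing, in which case the (false, true) substitution
#' interval applies downstream.
#'
#' @param diabetes_dx Logical vector: active diabetes diagnosis.
#' @param fasting_glucose Numeric vector (mmol/L), `NA` when no valid
#'   measurement.
#' @param missing_as_false Resolve no-evidence cases to `FALSE` (default).
#' @return Logical vector (with `NA` only when `missing_as_false = FALSE`).
#' @export
#' @examples
#' derive_diabetes(FALSE, 7.4)  # TRUE
#' derive_diabetes(FALSE, 5.1)  # FALSE
#' derive_diabetes(FALSE, NA)   # FALSE (missing means no diabetes)
derive_diabetes <- function(diabetes_dx, fasting_glucose,
                            missing_as_false = TRUE) {
  n <- max(length(diabetes_dx), length(fasting_glucose))
  dx <- rep_len(as.logical(diabetes_dx), n)
  glu <- rep_len(fasting_glucose, n)
  out <- rep(NA, n)
  out[dx %in% TRUE] <- TRUE
  out[!dx %in% TRUE & !is.na(glu)] <- glu[!dx %in% TRUE & !is.na(glu)] >= 7
  if (missing_as_false) out[is.na(out)] <- FALSE
  out
}

#' Resolve a parameter state into a minimum/maximum input pair
#'
#' Builds the two complete input vectors that bound the risk interval:
#' observed or derived parameters are copied into both vectors; missing
#' parameters are substituted by their extreme defaults ([clivd_defaults()]).
#' Category-valued evidence (alcohol categories, binned waist-hip ratio)
#' contributes its own `(min, max)` bounds. A valid GGT selects the `lab`
#' model variant; a missing GGT switches both ends to the `nonlab` variant.
#'
#' @param state A parameter-state tibble from [state_at()] or
#'   [merge_evidence()].
#' @param defaults Substitution defaults, see [clivd_defaults()].
#' @param diabetes_missing_as_false See [derive_diabetes()].
#' @param whr_scheme Optional [whr_bin_scheme()]: observed waist-hip ratios
#'   are replaced by their category's bounds (`"exact"` leaves them as-is).
#' @param check_age Error when a row's age lies outside `age_window`
#'   (such rows should have been removed by [screen_exclusions()]).
#' @param age_window Eligible age window used by `check_age`.
#' @return Tibble with one row per patient and query date: `sex`, `age`,
#'   `variant`, `ggt`, columns `<param>_min`/`<param>_max` for smoking,
#'   alcohol, whr and diabetes, and a `substituted` list-column naming the
#'   parameters replaced by defaults.
#' @export
resolve_inputs <- function(state, defaults = clivd_defaults(),
                           diabetes_missing_as_false = TRUE,
                           whr_scheme = NULL, check_age = TRUE,
                           age_window = c(40, 70)) {
  wide <- state |>
    select("patient_id", "query_date", "sex", "age", "parameter",
           "vmin", "vmax") |>
    tidyr::pivot_wider(names_from = "parameter",
                       values_from = c("vmin", "vmax"),
                       names_glue = "{parameter}_{.value}")
  n <- nrow(wide)
  if (check_age && any(wide$age < age_window[1] | wide$age > age_window[2])) {
    abort("age outside the eligible window; screen exclusions before resolving inputs")
  }
  col <- function(nm) if (nm %in% names(wide)) wide[[nm]] else rep(NA_real_, n)

  smoking_min <- col("smoking_vmin"); smoking_max <- col("smoking_vmax")
  alcohol_min <- col("alcohol_vmin"); alcohol_max <- col("alcohol_vmax")
  whr_min <- col("whr_vmin"); whr_max <- col("whr_vmax")
  ggt <- col("ggt_vmin")
  glucose <- col("fasting_glucose_vmin")
  dxdm <- !is.na(col("diabetes_dx_vmin"))

  sub_smoking <- is.na(smoking_min)
  sub_alcohol <- is.na(alcohol_min)
  sub_whr <- is.na(whr_min)
  smoking_min[sub_smoking] <- defaults$smoking[1]
  smoking_max[sub_smoking] <- defaults$smoking[2]
  alcohol_min[sub_alcohol] <- defaults$alcohol[1]
  alcohol_max[sub_alcohol] <- defaults$alcohol[2]

  if (!is.null(whr_scheme) && !identical(whr_scheme$name, "exact")) {
    obs <- !sub_whr
    if (any(obs)) {
      b <- bin_whr(whr_min[obs], whr_scheme)
      whr_min[obs] <- b$whr_min
      whr_max[obs] <- b$whr_max
    }
  }
  whr_min[sub_whr] <- defaults$whr[1]
  whr_max[sub_whr] <- defaults$whr[2]

  dm <- derive_diabetes(dxdm, glucose, missing_as_false = diabetes_missing_as_false)
  sub_diabetes <- is.na(dm)
  diabetes_min <- as.numeric(dm); diabetes_max <- as.numeric(dm)
  diabetes_min[sub_diabetes] <- defaults$diabetes[1]
  diabetes_max[sub_diabetes] <- defaults$diabetes[2]

  variant <- ifelse(is.na(ggt), "nonlab", "lab")

  tibble(
    patient_id = wide$patient_id, query_date = wide$query_date,
    sex = wide$sex, age = wide$age, variant = variant, ggt = ggt,
    smoking_min = smoking_min, smoking_max = smoking_max,
    alcohol_min = alcohol_min, alcohol_max = alcohol_max,
    whr_min = whr_min, whr_max = whr_max,
    diabetes_min = diabetes_min, diabetes_max = diabetes_max,
    substituted = purrr::pmap(
      list(sub_smoking, sub_alcohol, sub_whr, sub_diabetes, is.na(ggt)),
      function(s, a, w, d, g) {
        c("smoking", "alcohol", "whr", "diabetes", "ggt")[c(s, a, w, d, g)]
      })
  )
}

#' Compute the risk interval from a resolved input pair
#'
#' Scores the minimum-risk and maximum-risk input vectors with the CLivD risk
#' function. With all published coefficient signs non-negative in the ordered
#' inputs, the minimum vector can never out-score the maximum vector; an
#' internal consistency check guards against a non-monotone coefficient
#' transcription.
#'
#' @param inputs Output of [resolve_inputs()].
#' @param coefficients A [clivd_coefficients()] object.
#' @return `inputs` with columns `risk_min`, `risk_max` and `width`
#'   (`risk_max - risk_min`) appended.
#' @export
risk_interval <- function(inputs, coefficients = clivd_coefficients()) {
  mk <- function(which) {
    tibble(sex = inputs$sex, age = inputs$age,
           smoking = inputs[[paste0("smoking_", which)]],
           alcohol = inputs[[paste0("alcohol_", which)]],
           whr = inputs[[paste0("whr_", which)]],
           diabetes = inputs[[paste0("diabetes_", which)]],
           ggt = inputs$ggt, variant = inputs$variant)
  }
  risk_min <- clivd_score(mk("min"), coefficients)
  risk_max <- clivd_score(mk("max"), coefficients)
  if (any(risk_min > risk_max + 1e-12)) {
    abort("internal consistency error: minimum risk exceeds maximum risk; check the coefficient transcription for non-monotone terms")
  }
  inputs |>
    mutate(risk_min = risk_min, risk_max = risk_max,
           width = risk_max - risk_min)
}

#' Categorize a risk interval
#'
#' Assigns low / moderate / high / not-specified from the minimum and maximum
#' risk, with cutoffs at 5% and 10% by default: high iff the minimum risk is
#' at or above the high cutoff; else low iff the maximum risk is below the low
#' cutoff; else moderate iff the minimum risk is above the low cutoff; else
#' not specified (the interval spans the cutoffs, so no call can be made).
#' Total and single-valued over all valid intervals.
#'
#' @param risk_min,risk_max Numeric vectors, `0 <= risk_min <= risk_max <= 1`.
#' @param cutoffs Named numeric `c(low = 0.05, high = 0.10)`, `low < high`.
#' @return Factor with levels `low`, `moderate`, `high`, `not_specified`.
#' @export
#' @examples
#' categorize_risk(0.03, 0.04)  # low
#' categorize_risk(0.12, 0.15)  # high
#' categorize_risk(0.06, 0.08)  # moderate
#' categorize_risk(0.03, 0.20)  # not_specified
categorize_risk <- function(risk_min, risk_max,
                            cutoffs = c(low = 0.05, high = 0.10)) {
  if (cutoffs["low"] > cutoffs["high"]) abort("cutoffs must satisfy low <= high")
  if (any(risk_min > risk_max | risk_min < 0 | risk_max > 1)) {
    abort("invalid risk interval: need 0 <= risk_min <= risk_max <= 1")
  }
  out <- case_when(
    risk_min >= cutoffs["high"] ~ "high",
    risk_max < cutoffs["low"] ~ "low",
    risk_min > cutoffs["low"] ~ "moderate",
    TRUE ~ "not_specified"
  )
  factor(out, levels = c("low", "moderate", "high", "not_specified"))
}
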