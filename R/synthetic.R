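.occurrence_classes <- c("0", "1", "2-5", "6-10", "11-15", ">15")

# per-parameter occurrence histograms over a patient's whole record history:
# counts observed in a national patient data repository 2014-2022 (N = 96,200)
.default_occurrence_counts <- list(
  fasting_glucose     = c(84521, 9141, 2460, 64, 8, 6),
  height              = c(76815, 10923, 7752, 608, 82, 20),
  weight              = c(78003, 9007, 7311, 1364, 329, 186),
  bmi                 = c(80651, 8482, 6393, 567, 85, 22),
  waist_circumference = c(95812, 349, 39, 0, 0, 0),
  ggt                 = c(91891, 3144, 1067, 77, 12, 9),
  smoking_status      = c(96193, 7, 0, 0, 0, 0)
)

# alcohol- and smoking-related diagnosis event counts in the same repository
# (event counts, not patient counts), scaled by N = 96,200 into expected
# events per patient
.default_dx_counts <- tibble(
  system = c(rep("ICD-10", 8), "ICPC-2", "ICPC-2", "ICD-10", "ICPC-2"),
  code = c("F10.09", "F10.1", "F10.20", "F10.24", "F10.25", "F10.26",
           "F10.29", "F10.39", "P15", "P16", "Z72.0", "P17"),
  group = c(rep("alcohol", 10), "smoking", "smoking"),
  count = c(2158, 18141, 3697, 3251, 3921, 3328, 3268, 1690, 4494, 2417,
            1102, 465)
)

#' Synthetic cohort configuration
#'
#' Parameters of the synthetic patient-record generator. Defaults emulate the
#' marginal statistics of a national electronic health record repository
#' (96,200 adults, documents 2014 to mid-2022): per-parameter occurrence
#' histograms over occurrence classes 0/1/2-5/6-10/11-15/>15; alcohol- and
#' smoking-related diagnosis event rates; and Finnish free-text snippets
#' containing the extraction keywords. Under the defaults no structured
#' waist-hip-ratio or weekly-alcohol measurements are generated (neither is
#' available in structured form in the emulated repository). Latent per-person
#' risk-factor truth (smoker, drinking category, diabetes) is drawn first and
#' drives both diagnosis and text emission, enabling end-to-end recovery
#' tests.
#'
#' @param n_patients Cohort size (>= 1).
#' @param start_date,end_date Document date range.
#' @param p_male Probability of male sex.
#' @param age_range Age range (years, at `start_date`), uniform.
#' @param occurrence_counts Named list of length-6 occurrence-class count (or
#'   proportion) vectors per measurement parameter.
#' @param dx_counts Diagnosis event-count table (`system`, `code`, `group`,
#'   `count`); `count / dx_denominator` is the expected number of events per
#'   patient.
#' @param dx_denominator Denominator for scaling `dx_counts` (the emulated
#'   repository size).
#' @param p_smoker,drinker_probs Latent smoking prevalence and drinking
#'   category probabilities (`none`, `moderate`, `at_risk`, `heavy`).
#' @param p_diabetes,p_diabetes_dx Latent diabetes prevalence and probability
#'   that a diabetic carries a coded diagnosis.
#' @param exclusion_dx_rates Named per-patient probabilities of carrying an
#'   exclusion diagnosis (`liver`, `hepatitis`, `cancer`).
#' @param text_mean Mean number of free-text notes per patient (Poisson).
#' @param text_smoking_rate,text_alcohol_rate Per-note probability that the
#'   note mentions smoking status / alcohol use (matching the latent truth).
#' @param seed Optional integer seed (kept below 2^31); `NULL` uses the
#'   current RNG state.
#' @return A `clivd_cohort_config` list.
#' @export
cohort_config <- function(n_patients = 1000,
                          start_date = as.Date("2014-01-01"),
                          end_date = as.Date("2022-06-30"),
                          p_male = 0.5,
                          age_range = c(18, 85),
                          occurrence_counts = .default_occurrence_counts,
                          dx_counts = .default_dx_counts,
                          dx_denominator = 96200,
                          p_smoker = 0.22,
                          drinker_probs = c(none = 0.15, moderate = 0.60,
                                            at_risk = 0.15, heavy = 0.10),
                          p_diabetes = 0.08,
                          p_diabetes_dx = 0.6,
                          exclusion_dx_rates = c(liver = 0.004,
                                                 hepatitis = 0.0015,
                                                 cancer = 0.0005),
                          text_mean = 3,
                          text_smoking_rate = 0.10,
                          text_alcohol_rate = 0.10,
                          seed = NULL) {
  if (n_patients < 1) abort("`n_patients` must be >= 1")
  probs <- c(p_male, p_smoker, p_diabetes, p_diabetes_dx,
             text_smoking_rate, text_alcohol_rate, exclusion_dx_rates)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (abs(sum(drinker_probs) - 1) > 1e-8) abort("`drinker_probs` must sum to 1")
  for (nm in names(occurrence_counts)) {
    h <- occurrence_counts[[nm]]
    if (length(h) != length(.occurrence_classes) || any(h < 0) || sum(h) <= 0) {
      abort(sprintf("occurrence histogram for '%s' must be 6 non-negative counts", nm))
    }
  }
  structure(
    list(n_patients = n_patients, start_date = as.Date(start_date),
         end_date = as.Date(end_date), p_male = p_male, age_range = age_range,
         occurrence_counts = occurrence_counts, dx_counts = dx_counts,
         dx_denominator = dx_denominator, p_smoker = p_smoker,
         drinker_probs = drinker_probs, p_diabetes = p_diabetes,
         p_diabetes_dx = p_diabetes_dx, exclusion_dx_rates = exclusion_dx_rates,
         text_mean = text_mean, text_smoking_rate = text_smoking_rate,
         text_alcohol_rate = text_alcohol_rate, seed = seed),
    class = "clivd_cohort_config"
  )
}

.random_dates <- function(n, start, end) {
  start + sample.int(as.integer(end - start) + 1L, n, replace = TRUE) - 1L
}

.measurement_values <- function(parameter, n, sex, diabetic, smoker) {
  male <- sex == "male"
  v <- switch(parameter,
    height = round(rnorm(n, ifelse(male, 176, 163), ifelse(male, 7, 6.5)), 1),
    weight = round(pmax(rnorm(n, ifelse(male, 85, 71), ifelse(male, 15, 13)), 40), 1),
    bmi = round(pmin(pmax(rnorm(n, 27, 4.5), 15), 55), 1),
    waist_circumference = round(pmax(rnorm(n, ifelse(male, 98, 90), 11), 55), 1),
    ggt = round(pmax(exp(rnorm(n, log(30), 0.6)), 5)),
    fasting_glucose = round(pmax(ifelse(diabetic, rnorm(n, 7.8, 1.3),
                                        rnorm(n, 5.3, 0.5)), 3), 1),
    smoking_status = as.numeric(smoker),
    abort(sprintf("no value model for parameter '%s'", parameter))
  )
  v
}

# Finnish text snippets; the smoking/alcohol sentences contain the default
# extraction keywords, fillers contain none
.text_snippets <- list(
  filler = c("Potilas voi hyvin, ei erityistä.",
             "Kontrollikäynti sovitusti. Vointi ennallaan.",
             "Verenpaine seurannassa, jatkot sovitusti."),
  smoker = c("Tupakoi päivittäin noin askin.", "Tupakoi edelleen."),
  nonsmoker = c("Ei tupakoi.", "Tupakoimaton."),
  none = c("Ei käytä alkoholia.", "Ei juo alkoholia lainkaan."),
  moderate = c("Käyttää alkoholia kohtuullisesti viikonloppuisin."),
  at_risk = c("Käyttää alkoholia toistuvasti, määrät kasvaneet."),
  heavy = c("Runsasta alkoholin käyttöä pitkään.",
            "Alkoholivieroitus osastolla, katkaisuhoito aloitettu.")
)

#' Generate a synthetic patient cohort
#'
#' Draws a cohort whose marginal statistics follow the configuration: each
#' patient receives a per-parameter measurement count drawn from the
#' occurrence histogram (within-class counts uniform over the class range),
#' event dates uniform over the document range, diagnosis events at the
#' configured rates emitted from latent-compatible patients, and free-text
#' notes embedding the configured Finnish phrases. Output always passes
#' [validate_events()]; reproducible given `config$seed`. The latent
#' per-patient truth is attached as `attr(cohort, "latent")`.
#'
#' @param config A [cohort_config()].
#' @return A [clivd_cohort()].
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "clivd_cohort_config")) abort("`config` must be a cohort_config()")
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_patients
  id <- sprintf("P%06d", seq_len(n))
  sex <- ifelse(runif(n) < config$p_male, "male", "female")
  age0 <- runif(n, config$age_range[1], config$age_range[2])
  birth <- config$start_date - round(age0 * 365.25)
  patients <- tibble(patient_id = id, sex = sex, birth_date = birth)

  latent <- tibble(
    patient_id = id,
    smoker = runif(n) < config$p_smoker,
    drinker = sample(names(config$drinker_probs), n, replace = TRUE,
                     prob = config$drinker_probs),
    diabetes = runif(n) < config$p_diabetes
  )

  events <- list()

  # structured measurements from the occurrence histograms
  class_lo <- c(0L, 1L, 2L, 6L, 11L, 16L)
  class_hi <- c(0L, 1L, 5L, 10L, 15L, 25L)
  for (param in names(config$occurrence_counts)) {
    h <- config$occurrence_counts[[param]]
    cls <- sample.int(6L, n, replace = TRUE, prob = h / sum(h))
    cnt <- class_lo[cls] + floor(runif(n) * (class_hi[cls] - class_lo[cls] + 1L))
    idx <- rep.int(seq_len(n), cnt)
    if (length(idx) == 0) next
    events[[param]] <- tibble(
      patient_id = id[idx],
      date = .random_dates(length(idx), config$start_date, config$end_date),
      kind = "measurement", parameter = param,
      value = .measurement_values(param, length(idx), sex[idx],
                                  latent$diabetes[idx], latent$smoker[idx])
    )
  }

  # alcohol/smoking diagnoses: event counts Poisson at the configured marginal
  # rate, emitted only from latent-compatible patients
  for (i in seq_len(nrow(config$dx_counts))) {
    row <- config$dx_counts[i, ]
    lambda <- row$count / config$dx_denominator
    eligible <- if (row$group == "alcohol") latent$drinker == "heavy" else latent$smoker
    f <- mean(eligible)
    if (f == 0 || lambda == 0) next
    cnt <- integer(n)
    cnt[eligible] <- rpois(sum(eligible), lambda / f)
    idx <- rep.int(seq_len(n), cnt)
    if (length(idx) == 0) next
    events[[paste0("dx_", row$code)]] <- tibble(
      patient_id = id[idx],
      date = .random_dates(length(idx), config$start_date, config$end_date),
      kind = "diagnosis", system = row$system, code = row$code
    )
  }

  # diabetes diagnoses
  dm_dx <- which(latent$diabetes & runif(n) < config$p_diabetes_dx)
  if (length(dm_dx) > 0) {
    events$dx_dm <- tibble(
      patient_id = id[dm_dx],
      date = .random_dates(length(dm_dx), config$start_date, config$end_date),
      kind = "diagnosis", system = "ICD-10", code = "E11.9"
    )
  }

  # exclusion diagnoses (liver disease, viral hepatitis, liver cancer)
  excl_codes <- c(liver = "K70.3", hepatitis = "B18.2", cancer = "C22.0")
  for (g in names(config$exclusion_dx_rates)) {
    hit <- which(runif(n) < config$exclusion_dx_rates[[g]])
    if (length(hit) == 0) next
    events[[paste0("dx_excl_", g)]] <- tibble(
      patient_id = id[hit],
      date = .random_dates(length(hit), config$start_date, config$end_date),
      kind = "diagnosis", system = "ICD-10", code = excl_codes[[g]]
    )
  }

  # free-text notes
  n_text <- rpois(n, config$text_mean)
  idx <- rep.int(seq_len(n), n_text)
  if (length(idx) > 0) {
    pick <- function(key, k) sample(.text_snippets[[key]], k, replace = TRUE)
    m <- length(idx)
    base <- pick("filler", m)
    smoke_on <- runif(m) < config$text_smoking_rate
    alc_on <- runif(m) < config$text_alcohol_rate
    smoke_txt <- ifelse(latent$smoker[idx], pick("smoker", m), pick("nonsmoker", m))
    alc_txt <- vapply(latent$drinker[idx], function(d) sample(.text_snippets[[d]], 1),
                      character(1))
    txt <- paste0(base,
                  ifelse(smoke_on, paste0(" ", smoke_txt), ""),
                  ifelse(alc_on, paste0(" ", alc_txt), ""))
    events$texts <- tibble(
      patient_id = id[idx],
      date = .random_dates(m, config$start_date, config$end_date),
      kind = "text", text = txt
    )
  }

  cohort <- clivd_cohort(patients, bind_rows(events), validate = TRUE)
  attr(cohort, "latent") <- latent
  cohort
}

#' Occurrence histogram of a measurement parameter
#'
#' Counts patients by the number of times a parameter occurs in their record
#' history, using the occurrence classes 0 / 1 / 2-5 / 6-10 / 11-15 / >15.
#' The classes partition the cohort, so counts sum to the cohort size.
#'
#' @param cohort A [clivd_cohort()].
#' @param parameter A measurement parameter name.
#' @return Tibble with columns `class`, `n`.
#' @export
occurrence_histogram <- function(cohort, parameter) {
  if (!parameter %in% names(.clivd_parameters)) {
    abort(sprintf("unknown parameter '%s'", parameter))
  }
  cnt <- cohort$events |>
    filter(.data$kind == "measurement", .data$parameter == !!parameter) |>
    count(.data$patient_id)
  all_cnt <- cohort$patients |>
    left_join(cnt, by = "patient_id") |>
    mutate(n = coalesce(.data$n, 0L))
  cls <- cut(all_cnt$n, breaks = c(-1, 0, 1, 5, 10, 15, Inf),
             labels = .occurrence_classes)
  tibble(class = .occurrence_classes,
         n = as.integer(table(factor(cls, levels = .occurrence_classes))))
}
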