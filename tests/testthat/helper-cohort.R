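# Small hand-built cohorts used across tests.

mini_patients <- function() {
  tibble::tibble(
    patient_id = c("A", "B"),
    sex = c("male", "female"),
    birth_date = as.Date(c("1960-05-10", "1970-11-02"))
  )
}

# one measurement, one diagnosis, one text note per patient
mini_cohort <- function() {
  clivd_cohort(
    mini_patients(),
    tibble::tibble(
      patient_id = c("A", "A", "A", "B", "B"),
      date = as.Date(c("2015-03-01", "2014-01-01", "2016-06-15",
                       "2015-07-01", "2017-02-03")),
      kind = c("measurement", "diagnosis", "text", "measurement", "diagnosis"),
      parameter = c("weight", NA, NA, "ggt", NA),
      value = c(80, NA, NA, 35, NA),
      system = c(NA, "ICD-10", NA, NA, "ICPC-2"),
      code = c(NA, "F10.1", NA, NA, "P15"),
      text = c(NA, NA, "Ei tupakoi. Käyttää alkoholia kohtuullisesti.", NA, NA)
    )
  )
}

# single 50-ish year-old patient with chosen events; born 1970 -> age 45 in 2015
one_patient_cohort <- function(events = NULL, sex = "male",
                               birth = as.Date("1970-01-15")) {
  clivd_cohort(
    tibble::tibble(patient_id = "P1", sex = sex, birth_date = birth),
    events
  )
}

measurement <- function(date, parameter, value, patient_id = "P1") {
  tibble::tibble(patient_id = patient_id, date = as.Date(date),
                 kind = "measurement", parameter = parameter, value = value)
}
diagnosis <- function(date, code, system = "ICD-10", patient_id = "P1") {
  tibble::tibble(patient_id = patient_id, date = as.Date(date),
                 kind = "diagnosis", system = system, code = code)
}
text_note <- function(date, text, patient_id = "P1") {
  tibble::tibble(patient_id = patient_id, date = as.Date(date),
                 kind = "text", text = text)
}

# moderately sized generated cohort shared by the property tests (built once)
fixture_cohort <- local({
  cache <- NULL
  function(n = 400, seed = 20240901) {
    key <- paste(n, seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- generate_cohort(cohort_config(n_patients = n, seed = seed))
    }
    cache[[key]]
  }
})

# independent re-implementation of the risk function, reading the coefficient
# YAML directly; used as the transcription oracle
oracle_clivd_score <- function(sex, age, smoking, alcohol, whr, diabetes,
                               ggt = NA, variant = "nonlab",
                               path = system.file("extdata",
                                                  "clivd_coefficients_synthetic.yaml",
                                                  package = "clivdr")) {
  y <- yaml::read_yaml(path)$variants[[variant]]
  b <- y$coefficients
  ctr <- y$centering
  lp <- b$male * (sex == "male") +
    b$age_per_year * (age - ctr$age) +
    b$smoker * smoking +
    b$alcohol_per_serving_week * alcohol +
    b$whr_per_unit * (whr - ctr$whr) +
    b$diabetes * diabetes
  if (variant == "lab") lp <- lp + b$log_ggt * (log(ggt) - ctr$log_ggt)
  1 - y$baseline_survival^exp(lp)
}
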