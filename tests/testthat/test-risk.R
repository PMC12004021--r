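co_file <- clivd_coefficients()

test_that("clivd_score is deterministic and matches the transcription oracle", {
  set.seed(99)
  n <- 25
  cases <- tibble::tibble(
    sex = sample(c("male", "female"), n, TRUE),
    age = sample(40:70, n, TRUE),
    smoking = runif(n) < 0.5,
    alcohol = runif(n, 0, 49),
    whr = runif(n, 0.7, 1.3),
    diabetes = runif(n) < 0.3,
    ggt = exp(rnorm(n, log(30), 0.6)),
    variant = sample(c("lab", "nonlab"), n, TRUE)
  )
  got <- clivd_score(cases, co_file)
  want <- purrr::pmap_dbl(cases, oracle_clivd_score)
  expect_equal(got, want, tolerance = 1e-6)
  expect_identical(got, clivd_score(cases, co_file))
  expect_true(all(got >= 0 & got <= 1))
})

test_that("zeroed coefficients reduce the risk to the baseline term alone", {
  y <- yaml::read_yaml(co_file$path)
  for (v in c("nonlab", "lab")) {
    y$variants[[v]]$coefficients <- lapply(y$variants[[v]]$coefficients, \(x) 0)
  }
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(y, tmp)
  co0 <- clivd_coefficients(tmp)
  r <- clivd_score(data.frame(sex = c("male", "female"), age = c(40, 70),
                              smoking = c(TRUE, FALSE), alcohol = c(0, 49),
                              whr = c(0.7, 1.3), diabetes = c(TRUE, FALSE)),
                   co0, variant = "nonlab")
  expect_equal(r, rep(1 - y$variants$nonlab$baseline_survival, 2))
})

test_that("coefficient loading validates completeness and finiteness", {
  y <- yaml::read_yaml(co_file$path)
  y$variants$nonlab$coefficients$whr_per_unit <- NULL
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(y, tmp)
  expect_error(clivd_coefficients(tmp), "whr_per_unit")
  expect_error(clivd_coefficients("/nonexistent.yaml"), "not found")
})

test_that("scoring rejects incomplete inputs and unknown variants", {
  base <- data.frame(sex = "male", age = 50, smoking = TRUE, alcohol = 10,
                     whr = 1, diabetes = FALSE)
  expect_error(clivd_score(base, co_file, variant = "magic"), "variant")
  expect_error(clivd_score(transform(base, whr = NA), co_file), "missing")
  expect_error(clivd_score(base, co_file, variant = "lab"), "ggt")
  expect_silent(clivd_score(transform(base, ggt = 40), co_file, variant = "lab"))
})

test_that("exclusion screening applies the age window and diagnosis families", {
  mk <- function(birth, events = NULL) {
    clivd_cohort(tibble::tibble(patient_id = "P1", sex = "male",
                                birth_date = as.Date(birth)), events)
  }
  d <- as.Date("2020-06-01")
  # age 35 -> excluded by age alone
  e1 <- screen_exclusions(mk("1985-01-01"), d)
  expect_true(e1$excluded && e1$age_out_of_range)
  # age 55, liver diagnosis K70.3
  e2 <- screen_exclusions(mk("1965-01-01", diagnosis("2018-01-01", "K70.3")), d)
  expect_true(e2$liver_disease_dx && !e2$age_out_of_range)
  # C22.0 also counts as liver disease
  e2b <- screen_exclusions(mk("1965-01-01", diagnosis("2018-01-01", "C22.0")), d)
  expect_true(e2b$liver_disease_dx)
  # viral hepatitis B18.2
  e3 <- screen_exclusions(mk("1965-01-01", diagnosis("2019-05-01", "B18.2")), d)
  expect_true(e3$viral_hepatitis_dx)
  # age 55, no diagnoses -> eligible
  e4 <- screen_exclusions(mk("1965-01-01"), d)
  expect_false(e4$excluded)
  # ages 40 and 70 are inside the window, 39 and 71 outside
  expect_false(screen_exclusions(mk("1980-06-01"), d)$age_out_of_range)  # 40
  expect_false(screen_exclusions(mk("1950-06-01"), d)$age_out_of_range)  # 70
  expect_true(screen_exclusions(mk("1981-01-01"), d)$age_out_of_range)   # 39
  expect_true(screen_exclusions(mk("1949-05-01"), d)$age_out_of_range)   # 71
})

test_that("abstainer exclusion needs text confirmation by default", {
  ev_code <- diagnosis("2016-01-01", "F10.20")
  ev_text <- text_note("2017-01-01", "Ei käytä alkoholia enää.")
  mk <- function(ev) {
    clivd_cohort(tibble::tibble(patient_id = "P1", sex = "male",
                                birth_date = as.Date("1965-01-01")), ev)
  }
  d <- as.Date("2020-06-01")
  expect_false(screen_exclusions(mk(ev_code), d)$alcohol_abstainer_prior_use)
  expect_true(screen_exclusions(mk(dplyr::bind_rows(ev_code, ev_text)),
                                d)$alcohol_abstainer_prior_use)
  expect_true(screen_exclusions(mk(ev_code), d,
                                abstainer_mode = "code_only")$alcohol_abstainer_prior_use)
  expect_false(screen_exclusions(mk(dplyr::bind_rows(ev_code, ev_text)), d,
                                 abstainer_mode = "off")$alcohol_abstainer_prior_use)
})

test_that("diabetes derivation uses the 7 mmol/L fasting glucose threshold", {
  expect_true(derive_diabetes(FALSE, 7.4))
  expect_true(derive_diabetes(FALSE, 7.0))
  expect_false(derive_diabetes(FALSE, 5.1))
  expect_false(derive_diabetes(FALSE, NA))          # missing means no diabetes
  expect_true(derive_diabetes(TRUE, NA))            # diagnosis dominates
  expect_true(derive_diabetes(TRUE, 5.0))
  expect_true(is.na(derive_diabetes(FALSE, NA, missing_as_false = FALSE)))
})

test_that("resolve_inputs substitutes the published default extremes", {
  co <- one_patient_cohort(NULL, sex = "male", birth = as.Date("1965-06-01"))
  s <- state_at(co, as.Date("2015-12-31"))
  inp <- resolve_inputs(s)
  expect_equal(inp$smoking_min, 0); expect_equal(inp$smoking_max, 1)
  expect_equal(inp$alcohol_min, 0); expect_equal(inp$alcohol_max, 49)
  expect_equal(inp$whr_min, 0.7);  expect_equal(inp$whr_max, 1.3)
  expect_equal(inp$diabetes_min, 0); expect_equal(inp$diabetes_max, 0)
  expect_equal(inp$variant, "nonlab")
  expect_setequal(inp$substituted[[1]], c("smoking", "alcohol", "whr", "ggt"))

  # with missing-diabetes kept open, the (false, true) default applies
  inp2 <- resolve_inputs(s, diabetes_missing_as_false = FALSE)
  expect_equal(inp2$diabetes_min, 0); expect_equal(inp2$diabetes_max, 1)
  expect_true("diabetes" %in% inp2$substituted[[1]])
})

test_that("observed values enter both vectors and are not marked substituted", {
  co <- one_patient_cohort(
    measurement("2015-06-01", "alcohol_servings_per_week", 10),
    birth = as.Date("1965-06-01"))
  inp <- resolve_inputs(state_at(co, as.Date("2015-12-31")))
  expect_equal(inp$alcohol_min, 10)
  expect_equal(inp$alcohol_max, 10)
  expect_false("alcohol" %in% inp$substituted[[1]])
})

test_that("a valid GGT selects the lab variant; missing GGT the nonlab variant", {
  co <- one_patient_cohort(measurement("2015-06-01", "ggt", 80),
                           birth = as.Date("1965-06-01"))
  inp <- resolve_inputs(state_at(co, as.Date("2015-12-31")))
  expect_equal(inp$variant, "lab")
  expect_equal(inp$ggt, 80)
  # under the one-year policy the same measurement has expired two years on
  inp2 <- resolve_inputs(state_at(co, as.Date("2017-12-31"),
                                  lifecycle_policy("one_year")))
  expect_equal(inp2$variant, "nonlab")
})

test_that("resolve_inputs enforces prior exclusion screening on age", {
  co <- one_patient_cohort(NULL, birth = as.Date("1990-01-01"))  # age 25
  s <- state_at(co, as.Date("2015-12-31"))
  expect_error(resolve_inputs(s), "age")
  expect_silent(resolve_inputs(s, check_age = FALSE))
})

test_that("risk intervals: fully observed inputs give width zero", {
  co <- one_patient_cohort(dplyr::bind_rows(
    measurement("2015-01-01", "whr", 0.95),
    measurement("2015-02-01", "smoking_status", 1),
    measurement("2015-03-01", "alcohol_servings_per_week", 12),
    measurement("2015-04-01", "fasting_glucose", 5.0),
    measurement("2015-05-01", "ggt", 40)
  ), birth = as.Date("1965-06-01"))
  ri <- risk_interval(resolve_inputs(state_at(co, as.Date("2015-12-31"))), co_file)
  expect_equal(ri$width, 0)
  expect_equal(ri$risk_min, ri$risk_max)
})

test_that("observing a parameter narrows the interval (containment)", {
  co_none <- one_patient_cohort(NULL, birth = as.Date("1965-06-01"))
  co_alc <- one_patient_cohort(
    measurement("2015-06-01", "alcohol_servings_per_week", 10),
    birth = as.Date("1965-06-01"))
  d <- as.Date("2015-12-31")
  r_full <- risk_interval(resolve_inputs(state_at(co_none, d)), co_file)
  r_alc <- risk_interval(resolve_inputs(state_at(co_alc, d)), co_file)
  expect_lt(r_alc$width, r_full$width)
  expect_gte(r_alc$risk_min, r_full$risk_min)
  expect_lte(r_alc$risk_max, r_full$risk_max)
})

test_that("narrowing holds over a grid of observed values inside the defaults", {
  # replacing any substituted default by an in-range observation must yield a
  # contained interval, for each parameter separately
  d <- as.Date("2015-12-31")
  co_none <- one_patient_cohort(NULL, birth = as.Date("1965-06-01"))
  base <- risk_interval(resolve_inputs(state_at(co_none, d)), co_file)
  grids <- list(
    alcohol_servings_per_week = seq(0, 49, length.out = 7),
    whr = seq(0.7, 1.3, length.out = 7),
    smoking_status = c(0, 1)
  )
  for (param in names(grids)) {
    for (v in grids[[param]]) {
      co <- one_patient_cohort(measurement("2015-06-01", param, v),
                               birth = as.Date("1965-06-01"))
      ri <- risk_interval(resolve_inputs(state_at(co, d)), co_file)
      expect_gte(ri$risk_min, base$risk_min - 1e-12)
      expect_lte(ri$risk_max, base$risk_max + 1e-12)
    }
  }
})

test_that("categorization follows the cutoff table and decision order", {
  expect_equal(as.character(categorize_risk(0.03, 0.04)), "low")
  expect_equal(as.character(categorize_risk(0.12, 0.15)), "high")
  expect_equal(as.character(categorize_risk(0.06, 0.08)), "moderate")
  expect_equal(as.character(categorize_risk(0.03, 0.20)), "not_specified")
  # boundary semantics: max exactly at 5% is not low; min exactly 10% is high
  expect_equal(as.character(categorize_risk(0.05, 0.05)), "not_specified")
  expect_equal(as.character(categorize_risk(0.10, 0.10)), "high")
  expect_equal(as.character(categorize_risk(0.04, 0.049)), "low")
  # gap case: min below low cutoff, max between the cutoffs -> not specified
  expect_equal(as.character(categorize_risk(0.03, 0.08)), "not_specified")
})

test_that("categorization is total and single-valued on a dense grid", {
  g <- expand.grid(risk_min = seq(0, 1, by = 0.01),
                   risk_max = seq(0, 1, by = 0.01))
  g <- g[g$risk_min <= g$risk_max, ]
  cat <- categorize_risk(g$risk_min, g$risk_max)
  expect_false(anyNA(cat))
  expect_true(all(cat %in% c("low", "moderate", "high", "not_specified")))
  # with equal cutoffs the not-specified band vanishes for point intervals
  pts <- seq(0, 1, by = 0.01)
  cat_eq <- categorize_risk(pts, pts, cutoffs = c(low = 0.05, high = 0.05))
  expect_false(any(cat_eq == "not_specified"))
})

test_that("invalid intervals are rejected", {
  expect_error(categorize_risk(0.5, 0.4), "invalid risk interval")
  expect_error(categorize_risk(-0.1, 0.4), "invalid risk interval")
})
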