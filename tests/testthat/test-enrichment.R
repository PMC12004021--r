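test_that("heavy-alcohol diagnoses set the sex-specific serving floor", {
  m <- map_diagnoses(tibble::tibble(system = "ICD-10", code = "F10.1"), "male")
  expect_equal(m$alcohol_min, 23)
  expect_equal(m$alcohol_max, 49)
  f <- map_diagnoses(tibble::tibble(system = "ICPC-2", code = "P15"), "female")
  expect_equal(f$alcohol_min, 12)
  expect_equal(f$alcohol_max, 49)
})

test_that("smoking codes give the exact smoking input; unmapped codes nothing", {
  s <- map_diagnoses(tibble::tibble(system = "ICD-10", code = "Z72.0"), "male")
  expect_true(s$smoking)
  expect_true(is.na(s$alcohol_min))
  s2 <- map_diagnoses(tibble::tibble(system = "ICPC-2", code = "P17"), "female")
  expect_true(s2$smoking)
  none <- map_diagnoses(tibble::tibble(system = "ICD-10", code = "J45.9"), "male")
  expect_true(is.na(none$smoking))
  expect_true(is.na(none$alcohol_min))
  # family wildcard: any F10.2x dependence code counts as heavy use
  fam <- map_diagnoses(tibble::tibble(system = "ICD-10", code = "F10.26"), "male")
  expect_equal(fam$alcohol_min, 23)
})

test_that("a pattern mapping to two effects is rejected", {
  bad <- dplyr::bind_rows(code_mapping(),
                          tibble::tibble(system = "ICD-10", pattern = "Z72.0",
                                         effect = "alcohol_heavy"))
  expect_error(map_diagnoses(tibble::tibble(system = "ICD-10", code = "Z72.0"),
                             "male", mapping = bad), "two effects")
})

test_that("text extraction converts Finnish phrases into findings", {
  f1 <- extract_text_findings("ei käytä alkoholia")
  expect_equal(nrow(f1), 1)  # negation suppresses the overlapping use-pattern
  expect_equal(f1$kind, "alcohol_category")
  expect_equal(f1$category, "none")

  f2 <- extract_text_findings("Runsasta alkoholin käyttöä")
  expect_true(any(f2$category == "heavy"))

  f3 <- extract_text_findings("Potilas saapui katkaisuhoitoon.")
  expect_equal(f3$category, "heavy")

  f4 <- extract_text_findings("Tupakoi päivittäin")
  expect_equal(f4$kind, "smoking_positive")

  f5 <- extract_text_findings("Ei tupakoi.")
  expect_equal(f5$kind, "smoking_negative")

  expect_equal(nrow(extract_text_findings("Verenpaine koholla.")), 0)
})

test_that("pattern matching is pure and case-insensitive", {
  txt <- "EI KÄYTÄ ALKOHOLIA. tupakoi."
  a <- extract_text_findings(txt)
  b <- extract_text_findings(txt)
  expect_identical(a, b)
  expect_setequal(a$kind, c("alcohol_category", "smoking_positive"))
})

test_that("invalid user-supplied patterns fail at load time", {
  bad <- tibble::tibble(kind = "smoking_positive", pattern = "([unclosed",
                        category = NA_character_, priority = 1L)
  expect_error(extract_text_findings("x", bad), "invalid keyword regex")
  noname <- tibble::tibble(kind = "alcohol_category", pattern = "alkohol",
                           category = NA_character_, priority = 1L)
  expect_error(extract_text_findings("x", noname), "category name")
})

test_that("alcohol categories convert to bounds with THL-anchored heavy floors", {
  expect_equal(unname(alcohol_category_to_bounds("none", "male")), c(0, 0))
  expect_equal(unname(alcohol_category_to_bounds("heavy", "male")), c(23, 49))
  expect_equal(unname(alcohol_category_to_bounds("heavy", "female")), c(12, 49))
  expect_error(alcohol_category_to_bounds("binge", "male"), "unknown")
  tbl <- alcohol_categories()
  expect_true(all(tbl$servings_min <= tbl$servings_max))
  expect_true(all(tbl$servings_max <= 49))
})

test_that("evidence precedence is structured > text > diagnosis", {
  d <- as.Date("2020-12-31")
  birth <- as.Date("1965-06-01")
  # structured alcohol measurement beats a heavy diagnosis
  co1 <- one_patient_cohort(dplyr::bind_rows(
    measurement("2018-01-01", "alcohol_servings_per_week", 4),
    diagnosis("2019-01-01", "F10.1")
  ), birth = birth)
  s1 <- merge_evidence(co1, d)
  alc1 <- s1[s1$parameter == "alcohol", ]
  expect_equal(alc1$source, "structured")
  expect_equal(c(alc1$vmin, alc1$vmax), c(4, 4))

  # a later text abstinence finding beats an earlier heavy diagnosis
  co2 <- one_patient_cohort(dplyr::bind_rows(
    diagnosis("2015-01-01", "F10.1"),
    text_note("2019-01-01", "Ei käytä alkoholia.")
  ), birth = birth)
  s2 <- merge_evidence(co2, d)
  alc2 <- s2[s2$parameter == "alcohol", ]
  expect_equal(alc2$source, "text")
  expect_equal(c(alc2$vmin, alc2$vmax), c(0, 0))

  # text findings obey the measurement lifecycle: under the one-year policy
  # the 2019 note has expired by 2020-12-31 and the diagnosis resurfaces
  s3 <- merge_evidence(co2, d, lifecycle_policy("one_year"))
  alc3 <- s3[s3$parameter == "alcohol", ]
  expect_equal(alc3$source, "diagnosis")
  expect_equal(c(alc3$vmin, alc3$vmax), c(23, 49))

  # no evidence at all leaves the parameter missing
  co4 <- one_patient_cohort(NULL, birth = birth)
  s4 <- merge_evidence(co4, d)
  expect_equal(s4$source[s4$parameter == "alcohol"], "missing")
})

test_that("within a source the most recent valid finding wins", {
  co <- one_patient_cohort(dplyr::bind_rows(
    text_note("2016-01-01", "Runsasta alkoholin käyttöä."),
    text_note("2019-01-01", "Ei käytä alkoholia.")
  ), birth = as.Date("1965-06-01"))
  s <- merge_evidence(co, as.Date("2020-12-31"))
  alc <- s[s$parameter == "alcohol", ]
  expect_equal(c(alc$vmin, alc$vmax), c(0, 0))
  expect_equal(alc$source_date, as.Date("2019-01-01"))
})

test_that("enrichment never widens the risk interval (cohort property)", {
  co <- fixture_cohort(300)
  coefs <- clivd_coefficients()
  base_cfg <- pipeline_config(use_diagnoses = FALSE, use_text = FALSE,
                              coefficients = coefs)
  enr_cfg <- pipeline_config(use_diagnoses = TRUE, use_text = TRUE,
                             coefficients = coefs)
  dates <- as.Date(c("2016-12-31", "2020-12-31"))
  r0 <- cohort_risk(co, base_cfg, dates = dates)
  r1 <- cohort_risk(co, enr_cfg, dates = dates)
  j <- dplyr::inner_join(
    r0 |> dplyr::filter(eligible) |>
      dplyr::select("patient_id", "query_date", w0 = "width",
                    min0 = "risk_min", max0 = "risk_max"),
    r1 |> dplyr::filter(eligible) |>
      dplyr::select("patient_id", "query_date", w1 = "width",
                    min1 = "risk_min", max1 = "risk_max"),
    by = c("patient_id", "query_date"))
  expect_gt(nrow(j), 50)
  expect_true(all(j$w1 <= j$w0 + 1e-12))
  expect_true(all(j$min1 >= j$min0 - 1e-12))
  expect_true(all(j$max1 <= j$max0 + 1e-12))
})
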