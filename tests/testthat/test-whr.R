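test_that("WHR draws recover the sex-specific means and the literal variance", {
  sc_free <- whr_scenario(truncate = FALSE)
  n <- 1e5
  se_mean <- sqrt(0.07 / n)

  set.seed(101)
  m <- draw_whr(n, "male", sc_free)
  expect_lt(abs(mean(m) - 0.96), 4 * se_mean)
  set.seed(102)
  f <- draw_whr(n, "female", sc_free)
  expect_lt(abs(mean(f) - 0.84), 4 * se_mean)
  # sample variance close to the literal 0.07 (SE of var ~ var * sqrt(2/n))
  expect_lt(abs(var(m) - 0.07), 4 * 0.07 * sqrt(2 / n))

  # truncation to (0.3, 2.0) trims the lower tail, shifting the mean up a
  # little; the shift is bounded well under the truncated-normal bias
  set.seed(103)
  mt <- draw_whr(n, "male", whr_scenario())
  expect_gt(mean(mt), 0.96 - 4 * se_mean)
  expect_lt(mean(mt), 0.96 + 0.01)
  expect_true(all(mt > 0.3 & mt < 2.0))
})

test_that("the SD reinterpretation switch narrows the distribution", {
  set.seed(104)
  x <- draw_whr(2e4, "male", whr_scenario(variance_is_sd = TRUE))
  expect_lt(abs(stats::sd(x) - 0.07), 0.005)
})

test_that("draws are reproducible under a fixed seed", {
  sc <- whr_scenario()
  set.seed(42); a <- draw_whr(1000, rep(c("male", "female"), 500), sc)
  set.seed(42); b <- draw_whr(1000, rep(c("male", "female"), 500), sc)
  expect_identical(a, b)
})

test_that("document-coverage injection hits the configured fraction of event dates", {
  co <- fixture_cohort(400)
  n_dates <- nrow(dplyr::distinct(co$events, patient_id, date))
  expect_gt(n_dates, 1500)

  # coverage 0: unchanged; coverage 1: every event date carries WHR
  expect_identical(apply_whr_scenario(co, whr_scenario(coverage = 0))$events,
                   co$events)
  set.seed(7)
  full <- apply_whr_scenario(co, whr_scenario(coverage = 1))
  added_full <- dplyr::anti_join(full$events, co$events,
                                 by = names(co$events))
  expect_equal(nrow(added_full), n_dates)

  set.seed(8)
  part <- apply_whr_scenario(co, whr_scenario(coverage = 0.10))
  added <- nrow(part$events) - nrow(co$events)
  tol <- 4 * sqrt(0.10 * 0.90 / n_dates)
  expect_lt(abs(added / n_dates - 0.10), tol)
})

test_that("scenario injection adds only simulated whr events, originals untouched", {
  co <- fixture_cohort(150)
  set.seed(9)
  out <- apply_whr_scenario(co, whr_scenario(coverage = 0.2))
  added <- dplyr::filter(out$events, source == "simulated")
  expect_gt(nrow(added), 0)
  expect_true(all(added$parameter == "whr"))
  expect_true(all(added$value > 0.3 & added$value < 2.0))
  # original events pass through untouched (ordering within patient preserved)
  expect_equal(dplyr::filter(out$events, source != "simulated"), co$events)
  expect_equal(nrow(validate_events(out)), 0)
})

test_that("self-report modes add one WHR per age-eligible patient", {
  co <- fixture_cohort(150)
  set.seed(10)
  out <- apply_whr_scenario(co, whr_scenario(mode = "self_report_exact"))
  added <- dplyr::anti_join(out$events, co$events, by = names(co$events))
  expect_equal(anyDuplicated(added$patient_id), 0)
  ages <- age_at(
    co$patients$birth_date[match(added$patient_id, co$patients$patient_id)],
    added$date)
  expect_true(all(ages >= 40 & ages <= 70))
})

test_that("bin schemes return enclosing bounds; exact is the identity", {
  expect_equal(bin_whr(0.96), tibble::tibble(whr_min = 0.96, whr_max = 0.96))
  three <- whr_bin_scheme("three_bin")
  expect_equal(bin_whr(0.96, three), tibble::tibble(whr_min = 0.85, whr_max = 1.00))
  # outer bins clamp to the substitution defaults
  expect_equal(bin_whr(0.75, three), tibble::tibble(whr_min = 0.70, whr_max = 0.85))
  expect_equal(bin_whr(1.20, three), tibble::tibble(whr_min = 1.00, whr_max = 1.30))
  # but a value outside the clamp still lies inside its returned interval
  b <- bin_whr(c(0.5, 1.6), three)
  expect_true(all(b$whr_min <= c(0.5, 1.6) & c(0.5, 1.6) <= b$whr_max))
  expect_error(bin_whr(2.5, three), "physiological range")
})

test_that("five-bin intervals nest inside three-bin intervals inside the default", {
  three <- whr_bin_scheme("three_bin")
  five <- whr_bin_scheme("five_bin")
  v <- seq(0.705, 1.295, by = 0.005)
  b3 <- bin_whr(v, three)
  b5 <- bin_whr(v, five)
  expect_true(all(b5$whr_min >= b3$whr_min & b5$whr_max <= b3$whr_max))
  expect_true(all(b3$whr_min >= 0.7 & b3$whr_max <= 1.3))
  expect_true(all(b5$whr_min <= v & v <= b5$whr_max))
})

test_that("finer WHR information never widens cohort risk intervals", {
  co <- fixture_cohort(300)
  schemes <- c("three_bin", "five_bin", "exact")
  widths <- lapply(schemes, function(s) {
    cfg <- pipeline_config(
      whr_scenario = whr_scenario(coverage = 0.10, scheme = s),
      seed = 77)
    cohort_risk(co, cfg, dates = as.Date("2020-12-31")) |>
      dplyr::filter(eligible) |>
      dplyr::select("patient_id", "width")
  })
  no_whr <- cohort_risk(co, pipeline_config(),
                        dates = as.Date("2020-12-31")) |>
    dplyr::filter(eligible) |> dplyr::select("patient_id", w_none = "width")
  j <- Reduce(function(a, b) dplyr::inner_join(a, b, by = "patient_id"),
              list(no_whr,
                   dplyr::rename(widths[[1]], w3 = "width"),
                   dplyr::rename(widths[[2]], w5 = "width"),
                   dplyr::rename(widths[[3]], wx = "width")))
  # same seed => same simulated values; refinement can only narrow
  expect_true(all(j$w3 <= j$w_none + 1e-12))
  expect_true(all(j$w5 <= j$w3 + 1e-12))
  expect_true(all(j$wx <= j$w5 + 1e-12))
  expect_lt(mean(j$wx), mean(j$w_none))
})

test_that("scenario validation rejects out-of-range parameters", {
  expect_error(whr_scenario(coverage = 1.5), "coverage")
  expect_error(whr_scenario(male_mean = 1.6), "means")
  expect_error(whr_scenario(variance = 0), "variance")
})
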