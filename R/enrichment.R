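#' Default alcohol-use category table
#'
#' Categories for converting free-text alcohol findings into weekly-serving
#' bounds, anchored at the Finnish (THL) hazardous-drinking limits of about
#' 23 weekly servings for men and 12 for women: the `heavy` category floors at
#' those limits and is capped at 49 servings/week, the ceiling used when the
#' input is substituted by defaults. The intermediate category boundaries are
#' package defaults (the category concept is standard; exact bins are
#' configurable).
#'
#' @return Tibble with columns `name`, `sex`, `servings_min`, `servings_max`.
#' @export
alcohol_categories <- function() {
  tibble(
    name = rep(c("none", "moderate", "at_risk", "heavy"), each = 2),
    sex  = rep(c("male", "female"), times = 4),
    servings_min = c(0, 0, 1, 1, 14, 7, 23, 12),
    servings_max = c(0, 0, 13, 6, 22, 11, 49, 49)
  )
}

#' Convert an alcohol-use category to weekly-serving bounds
#'
#' The minimum bound feeds the minimum-risk calculation and the maximum bound
#' the maximum-risk calculation.
#'
#' @param category Category name (e.g. `"none"`, `"heavy"`).
#' @param sex `"male"` or `"female"`.
#' @param table Category table, see [alcohol_categories()].
#' @return Named numeric vector `c(servings_min, servings_max)`.
#' @export
#' @examples
#' alcohol_category_to_bounds("heavy", "male")    # 23, 49
#' alcohol_category_to_bounds("heavy", "female")  # 12, 49
alcohol_category_to_bounds <- function(category, sex, table = alcohol_categories()) {
  row <- table[table$name == category & table$sex == sex, ]
  if (nrow(row) != 1) {
    abort(sprintf("unknown alcohol category '%s' for sex '%s'", category, sex))
  }
  c(servings_min = row$servings_min, servings_max = row$servings_max)
}

#' Default diagnosis-code mapping
#'
#' Maps ICD-10 / ICPC-2 codes (with `X` family wildcards) to risk-model
#' evidence. Tobacco-use codes give the exact smoking input (the risk model
#' does not use cigarette counts); alcohol-dependence and abuse codes mark
#' heavy alcohol use, which sets the sex-specific weekly-servings floor (23
#' men / 12 women) while the ceiling stays at the 49-servings substitution
#' default.
#'
#' @return Tibble with columns `system`, `pattern`, `effect` (one of
#'   `smoker_true`, `alcohol_heavy`, `abstainer_flag`).
#' @export
code_mapping <- function() {
  m <- tibble(
    system = c("ICD-10", "ICD-10", "ICD-10", "ICD-10",
               "ICPC-2", "ICPC-2", "ICD-10", "ICPC-2"),
    pattern = c("F10.0X", "F10.1X", "F10.2X", "F10.3X",
                "P15", "P16", "Z72.0", "P17"),
    effect = c("alcohol_heavy", "alcohol_heavy", "alcohol_heavy", "alcohol_heavy",
               "alcohol_heavy", "alcohol_heavy", "smoker_true", "smoker_true")
  )
  .validate_code_mapping(m)
  m
}

.validate_code_mapping <- function(mapping) {
  ok_effects <- c("smoker_true", "alcohol_heavy", "abstainer_flag")
  if (any(!mapping$effect %in% ok_effects)) {
    abort(paste0("unknown mapping effect; must be one of ",
                 paste(ok_effects, collapse = ", ")))
  }
  key <- paste(mapping$system, mapping$pattern)
  multi <- tapply(mapping$effect, key, function(e) length(unique(e)) > 1)
  if (any(multi)) {
    abort(sprintf("pattern maps to two effects: %s", names(multi)[multi][1]))
  }
  invisible(mapping)
}

# THL-style hazardous-use floors by sex (weekly servings)
.heavy_alcohol_floor <- c(male = 23, female = 12)
.alcohol_ceiling <- 49

#' Map active diagnoses to risk-model evidence
#'
#' @param diagnoses Tibble with columns `system`, `code` (e.g. from
#'   [active_diagnoses()] for one patient).
#' @param sex `"male"` or `"female"` (selects the heavy-use serving floor).
#' @param mapping A [code_mapping()] table.
#' @return A list with elements `smoking` (`TRUE` or `NA`), `alcohol_min`,
#'   `alcohol_max` (numeric or `NA` when no alcohol evidence) and
#'   `abstainer_flag` (logical).
#' @export
#' @examples
#' map_diagnoses(tibble::tibble(system = "ICD-10", code = "F10.1"), "male")
map_diagnoses <- function(diagnoses, sex, mapping = code_mapping()) {
  .validate_code_mapping(mapping)
  effects <- character()
  if (nrow(diagnoses) > 0) {
    for (i in seq_len(nrow(mapping))) {
      hit <- diagnoses$system == mapping$system[i] &
        code_matches(diagnoses$code, mapping$pattern[i])
      if (any(hit)) effects <- c(effects, mapping$effect[i])
    }
  }
  heavy <- "alcohol_heavy" %in% effects
  list(
    smoking = if ("smoker_true" %in% effects) TRUE else NA,
    alcohol_min = if (heavy) unname(.heavy_alcohol_floor[sex]) else NA_real_,
    alcohol_max = if (heavy) .alcohol_ceiling else NA_real_,
    abstainer_flag = "abstainer_flag" %in% effects
  )
}

#' Default free-text keyword table
#'
#' Regex patterns applied case-insensitively to Finnish clinical narrative.
#' The alcohol patterns are the canonical keyword set for this extraction
#' task: a negation stem (maps to the `none` category), a heavy-use stem, and
#' a withdrawal/intoxication alternation (both map to `heavy`), plus a generic
#' use stem (maps to `moderate`). The smoking stems are package defaults and
#' fully editable. `priority` resolves overlapping matches: a lower number
#' wins and suppresses overlapping lower-priority matches, so "ei käytä
#' alkoholia" yields only the negation finding.
#'
#' @return Tibble with columns `kind`, `pattern`, `category`, `priority`.
#' @export
clivd_keywords <- function() {
  tibble(
    kind = c("alcohol_category", "alcohol_category", "alcohol_category",
             "alcohol_category", "smoking_negative", "smoking_positive"),
    pattern = c(
      "ei\\s*\\w*\\s*alkohol",
      "runsa\\w*\\s*alkohol",
      "vieroitus|vierotus|päihtymys|putki|katkaisu",
      "käytt?ä\\w*\\s*alkohol",
      "ei\\s+tupakoi|tupakoimaton|lopettanut\\s+tupakoinnin",
      "tupakoi"
    ),
    category = c("none", "heavy", "heavy", "moderate", NA, NA),
    priority = c(1L, 2L, 2L, 3L, 1L, 2L)
  )
}

.validate_keywords <- function(keyword_table) {
  req <- c("kind", "pattern", "category", "priority")
  if (!all(req %in% names(keyword_table))) {
    abort(paste0("keyword table must have columns: ", paste(req, collapse = ", ")))
  }
  for (p in keyword_table$pattern) {
    ok <- tryCatch({
      stringr::str_detect("", stringr::regex(p, ignore_case = TRUE)); TRUE
    }, error = function(e) FALSE)
    if (!ok) abort(sprintf("invalid keyword regex: '%s'", p))
  }
  bad <- keyword_table$kind == "alcohol_category" & is.na(keyword_table$category)
  if (any(bad)) abort("alcohol_category patterns must carry a category name")
  invisible(keyword_table)
}

#' Extract findings from free text
#'
#' Case-insensitive regex keyword search over a clinical note, converting
#' matched phrases into smoking-status and alcohol-use-category findings.
#' Matching is pure: the same text and table always yield the same findings.
#' Overlapping matches are resolved by pattern priority (negations outrank
#' positives), so a negated phrase produces a single negative finding.
#'
#' @param text Character vector of notes (one finding set per element).
#' @param keyword_table See [clivd_keywords()].
#' @return Tibble with columns `text_index`, `kind` (`smoking_positive`,
#'   `smoking_negative`, `alcohol_category`), `category` (for alcohol
#'   findings), `matched_span`.
#' @export
#' @examples
#' extract_text_findings("ei käytä alkoholia")        # alcohol category 'none'
#' extract_text_findings("Runsasta alkoholin käyttöä")  # 'heavy'
extract_text_findings <- function(text, keyword_table = clivd_keywords()) {
  .validate_keywords(keyword_table)
  kt <- keyword_table |> arrange(.data$priority)
  out <- purrr::imap(text, function(txt, idx) {
    spans <- list()
    rows <- list()
    for (i in seq_len(nrow(kt))) {
      loc <- stringr::str_locate_all(
        txt, stringr::regex(kt$pattern[i], ignore_case = TRUE))[[1]]
      if (nrow(loc) == 0) next
      for (j in seq_len(nrow(loc))) {
        s <- loc[j, 1]; e <- loc[j, 2]
        overlaps <- any(vapply(spans, function(sp) s <= sp[2] && e >= sp[1],
                               logical(1)))
        if (overlaps) next
        spans[[length(spans) + 1L]] <- c(s, e)
        rows[[length(rows) + 1L]] <- tibble(
          text_index = idx, kind = kt$kind[i], category = kt$category[i],
          matched_span = substr(txt, s, e)
        )
      }
    }
    bind_rows(rows)
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(text_index = integer(), kind = character(),
                  category = character(), matched_span = character())
  }
  res
}

# text findings for all text events of a cohort, as evidence rows
.text_evidence <- function(cohort, keyword_table = clivd_keywords(),
                           categories = alcohol_categories()) {
  te <- cohort$events |> mutate(.row = row_number()) |>
    filter(.data$kind == "text")
  if (nrow(te) == 0) return(NULL)
  f <- extract_text_findings(te$text, keyword_table)
  if (nrow(f) == 0) return(NULL)
  f <- f |>
    mutate(patient_id = te$patient_id[.data$text_index],
           source_date = te$date[.data$text_index],
           .row = te$.row[.data$text_index]) |>
    left_join(cohort$patients |> select("patient_id", "sex"), by = "patient_id")

  smoking <- f |> filter(.data$kind %in% c("smoking_positive", "smoking_negative")) |>
    transmute(.data$patient_id, .data$source_date, parameter = "smoking",
              vmin = as.numeric(.data$kind == "smoking_positive"),
              vmax = as.numeric(.data$kind == "smoking_positive"),
              source = "text", lifecycle_class = "measurement", .data$.row)

  alc <- f |> filter(.data$kind == "alcohol_category")
  alc_rows <- NULL
  if (nrow(alc) > 0) {
    bounds <- purrr::map2(alc$category, alc$sex, alcohol_category_to_bounds,
                          table = categories)
    alc_rows <- tibble(
      patient_id = alc$patient_id, source_date = alc$source_date,
      parameter = "alcohol",
      vmin = purrr::map_dbl(bounds, 1), vmax = purrr::map_dbl(bounds, 2),
      source = "text", lifecycle_class = "measurement", .row = alc$.row
    )
  }
  bind_rows(smoking, alc_rows)
}

# diagnosis-derived smoking/alcohol evidence rows for a cohort
.diagnosis_evidence <- function(cohort, mapping = code_mapping()) {
  .validate_code_mapping(mapping)
  d <- cohort$events |> mutate(.row = row_number()) |>
    filter(.data$kind == "diagnosis") |>
    left_join(cohort$patients |> select("patient_id", "sex"), by = "patient_id")
  if (nrow(d) == 0) return(NULL)
  rows <- list()
  for (i in seq_len(nrow(mapping))) {
    hit <- d$system == mapping$system[i] & code_matches(d$code, mapping$pattern[i])
    if (!any(hit)) next
    h <- d[hit, ]
    rows[[length(rows) + 1L]] <- switch(
      mapping$effect[i],
      smoker_true = tibble(
        patient_id = h$patient_id, source_date = h$date, parameter = "smoking",
        vmin = 1, vmax = 1, source = "diagnosis",
        lifecycle_class = "diagnosis", .row = h$.row),
      alcohol_heavy = tibble(
        patient_id = h$patient_id, source_date = h$date, parameter = "alcohol",
        vmin = unname(.heavy_alcohol_floor[h$sex]), vmax = .alcohol_ceiling,
        source = "diagnosis", lifecycle_class = "diagnosis", .row = h$.row),
      abstainer_flag = NULL
    )
  }
  if (length(rows) == 0) return(NULL)
  bind_rows(rows)
}

# Full evidence table for a cohort under the enrichment toggles.
build_evidence <- function(cohort, use_diagnoses = TRUE, use_text = TRUE,
                           mapping = code_mapping(),
                           keyword_table = clivd_keywords(),
                           categories = alcohol_categories()) {
  bind_rows(
    .structured_evidence(cohort),
    .diabetes_dx_evidence(cohort),
    if (use_diagnoses) .diagnosis_evidence(cohort, mapping),
    if (use_text) .text_evidence(cohort, keyword_table, categories)
  )
}

#' Merge structured, diagnosis-derived and text-derived evidence into a state
#'
#' Resolves the enriched parameter state at a query date. Source precedence is
#' structured > text > diagnosis for smoking and alcohol (structured values
#' are professionally recorded exact inputs; diagnoses are coarse
#' approximations); within a source the most recent valid finding wins.
#' Text-derived findings obey the measurement lifecycle (habits change);
#' diagnosis-derived evidence has infinite validity.
#'
#' @inheritParams state_at
#' @param use_diagnoses,use_text Enrichment toggles.
#' @param mapping A [code_mapping()] table.
#' @param keyword_table A [clivd_keywords()] table.
#' @param categories An [alcohol_categories()] table.
#' @return A parameter-state tibble as in [state_at()].
#' @export
merge_evidence <- function(cohort, date, policy = lifecycle_policy(),
                           use_diagnoses = TRUE, use_text = TRUE,
                           mapping = code_mapping(),
                           keyword_table = clivd_keywords(),
                           categories = alcohol_categories(),
                           under_18 = c("error", "drop")) {
  ev <- build_evidence(cohort, use_diagnoses, use_text, mapping,
                       keyword_table, categories)
  state_at(cohort, date, policy, evidence = ev, under_18 = match.arg(under_18))
}
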