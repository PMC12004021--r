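#' Construct a patient cohort from patients and events tables
#'
#' A cohort is the package's container for longitudinal patient records: a
#' `patients` tibble of fixed demographics and an `events` tibble of dated
#' records (measurements, diagnoses, free-text notes). Events are kept sorted
#' by patient, date and file order; same-date ties are permitted and resolved
#' downstream (last record wins).
#'
#' @param patients Data frame with columns `patient_id` (character, unique),
#'   `sex` (`"male"`/`"female"`) and `birth_date` (`Date`).
#' @param events Data frame with columns `patient_id`, `date` (`Date`),
#'   `kind` (`"measurement"`, `"diagnosis"` or `"text"`) and the kind-specific
#'   payload columns `parameter`, `value` (measurements), `system`, `code`
#'   (diagnoses), `text` (notes). An optional `source` column distinguishes
#'   `"structured"` records from `"simulated"` ones; it defaults to
#'   `"structured"`.
#' @param validate If `TRUE` (default), reject cohorts with invariant
#'   violations (see [validate_events()]).
#' @return An object of class `clivd_cohort`: a list with tibbles `patients`
#'   and `events`.
#' @seealso [read_events()], [write_events()], [validate_events()]
#' @export
clivd_cohort <- function(patients, events = NULL, validate = TRUE) {
  patients <- as_tibble(patients)
  req <- c("patient_id", "sex", "birth_date")
  if (!all(req %in% names(patients))) {
    abort(paste0("`patients` must have columns: ", paste(req, collapse = ", ")))
  }
  patients <- patients |>
    mutate(patient_id = as.character(.data$patient_id),
           birth_date = as.Date(.data$birth_date)) |>
    arrange(.data$patient_id)

  if (is.null(events) || nrow(as_tibble(events)) == 0L) {
    events <- tibble(
      patient_id = character(), date = as.Date(character()),
      kind = character(), parameter = character(), value = numeric(),
      system = character(), code = character(), text = character(),
      source = character()
    )
  }
  events <- as_tibble(events)
  for (col in c("parameter", "system", "code", "text", "source")) {
    if (!col %in% names(events)) events[[col]] <- NA_character_
  }
  if (!"value" %in% names(events)) events$value <- NA_real_
  events <- events |>
    mutate(
      patient_id = as.character(.data$patient_id),
      date = as.Date(.data$date),
      source = coalesce(.data$source, "structured")
    ) |>
    select("patient_id", "date", "kind", "parameter", "value",
           "system", "code", "text", "source") |>
    arrange(.data$patient_id, .data$date)

  out <- structure(list(patients = patients, events = events),
                   class = "clivd_cohort")
  if (validate) {
    v <- validate_events(out)
    if (nrow(v) > 0L) {
      abort(c("Cohort has invariant violations:",
              utils::head(paste0(v$patient_id, ": ", v$rule, " - ", v$detail), 5)))
    }
  }
  out
}

#' @export
print.clivd_cohort <- function(x, ...) {
  cat(sprintf("<clivd_cohort> %d patients, %d events", nrow(x$patients), nrow(x$events)))
  if (nrow(x$events) > 0) {
    cat(sprintf(" (%s to %s)", min(x$events$date), max(x$events$date)))
  }
  cat("\n")
  kinds <- table(x$events$kind)
  if (length(kinds)) {
    cat("  ", paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.clivd_cohort <- function(x, ...) {
  left_join(x$events, x$patients, by = "patient_id")
}

#' Validate cohort invariants
#'
#' Checks every type invariant of the record model and returns violations as
#' data, never raising: unique patient ids; known sex values; events dated on
#' or after the patient's birth date; known measurement parameters;
#' non-negative numeric values; waist-hip ratio inside (0.3, 2.0); boolean
#' smoking status; diagnosis code syntax matching its coding system; non-empty
#' free text.
#'
#' @param cohort A [clivd_cohort()], or a bare list with `patients`/`events`.
#' @return A tibble with columns `patient_id`, `rule`, `detail`; zero rows iff
#'   all invariants hold. The input is never modified.
#' @export
validate_events <- function(cohort) {
  patients <- as_tibble(cohort$patients)
  events <- as_tibble(cohort$events)
  v <- list()
  add <- function(ids, rule, detail) {
    if (length(ids) > 0) {
      v[[length(v) + 1L]] <<- tibble(patient_id = ids, rule = rule, detail = detail)
    }
  }

  dup <- patients$patient_id[duplicated(patients$patient_id)]
  add(unique(dup), "unique_patient_id", "duplicated patient_id")
  bad_sex <- patients$patient_id[!patients$sex %in% .clivd_sexes]
  add(bad_sex, "sex_enum", "sex must be 'male' or 'female'")
  add(patients$patient_id[is.na(patients$birth_date)], "birth_date", "missing birth_date")

  if (nrow(events) > 0) {
    orphan <- setdiff(unique(events$patient_id), patients$patient_id)
    add(orphan, "known_patient", "event for patient_id with no demographics record")

    ev <- left_join(events, patients, by = "patient_id")
    pre_birth <- ev$patient_id[!is.na(ev$birth_date) & ev$date < ev$birth_date]
    add(unique(pre_birth), "event_after_birth", "event dated before birth_date")

    bad_kind <- ev$patient_id[!ev$kind %in% c("measurement", "diagnosis", "text")]
    add(unique(bad_kind), "kind_enum", "unknown event kind")

    m <- ev[ev$kind == "measurement", ]
    unk <- m$patient_id[!m$parameter %in% names(.clivd_parameters)]
    add(unique(unk), "known_parameter",
        paste0("unknown measurement parameter: ",
               paste(unique(m$parameter[!m$parameter %in% names(.clivd_parameters)]),
                     collapse = ", ")))
    m <- m[m$parameter %in% names(.clivd_parameters), ]
    add(m$patient_id[is.na(m$value)], "value_present", "measurement without a value")
    neg <- m$patient_id[!is.na(m$value) & m$value < 0]
    add(neg, "value_nonnegative", "negative measurement value")
    w <- m[m$parameter == "whr" & !is.na(m$value), ]
    bad_whr <- w$patient_id[w$value <= .clivd_whr_range[1] | w$value >= .clivd_whr_range[2]]
    add(bad_whr, "whr_range", "whr outside (0.3, 2.0)")
    s <- m[m$parameter == "smoking_status" & !is.na(m$value), ]
    add(s$patient_id[!s$value %in% c(0, 1)], "smoking_boolean",
        "smoking_status must be boolean (0/1)")

    d <- ev[ev$kind == "diagnosis", ]
    bad_sys <- d$patient_id[!d$system %in% c("ICD-10", "ICPC-2")]
    add(unique(bad_sys), "system_enum", "diagnosis system must be ICD-10 or ICPC-2")
    d2 <- d[d$system %in% c("ICD-10", "ICPC-2"), ]
    bad_code <- d2[is.na(d2$code) | !.code_syntax_ok(d2$system, d2$code), ]
    add(bad_code$patient_id, "code_syntax",
        paste0("code does not match its system's syntax: ",
               coalesce(bad_code$code, "<missing>")))

    t <- ev[ev$kind == "text", ]
    add(t$patient_id[is.na(t$text) | !nzchar(t$text)], "text_nonempty", "empty text event")
  }

  if (length(v) == 0) {
    return(tibble(patient_id = character(), rule = character(), detail = character()))
  }
  bind_rows(v)
}

.events_header <- "patient_id\tdate\tkind\tdetail\tvalue\tsource"

.escape_field <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}
.unescape_field <- function(x) {
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

#' Write a cohort to the line-delimited event file format
#'
#' One record per line, tab-separated, with a fixed header. Demographics are
#' stored as `patient` records (date = birth date, detail = sex); measurement
#' records carry the parameter name and value, diagnosis records the coding
#' system and code, text records the (escaped) free text. Output ordering is
#' deterministic: patient id, then the patient record, then events by date in
#' input order, so [read_events()] followed by `write_events()` reproduces a
#' canonical file byte-for-byte.
#'
#' @param cohort A [clivd_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(cohort, path) {
  if (anyDuplicated(cohort$patients$patient_id)) {
    abort("duplicate patient_id in cohort; ids must be unique")
  }
  v <- validate_events(cohort)
  if (nrow(v) > 0) {
    abort(c("refusing to write an invalid cohort:",
            utils::head(paste0(v$patient_id, ": ", v$rule), 5)))
  }
  p <- cohort$patients |> arrange(.data$patient_id)
  plines <- tibble(
    patient_id = p$patient_id, date = as.character(p$birth_date),
    kind = "patient", detail = p$sex, value = "", source = "", ord = 0L
  )
  e <- cohort$events |> mutate(.row = row_number()) |>
    arrange(.data$patient_id, .data$date, .data$.row)
  elines <- tibble(
    patient_id = e$patient_id, date = as.character(e$date), kind = e$kind,
    detail = case_when(e$kind == "measurement" ~ e$parameter,
                       e$kind == "diagnosis" ~ e$system,
                       TRUE ~ ""),
    value = case_when(
      e$kind == "measurement" & e$parameter == "smoking_status" ~
        as.character(ifelse(e$value == 1, "true", "false")),
      e$kind == "measurement" ~ .fmt_num(e$value),
      e$kind == "diagnosis" ~ e$code,
      TRUE ~ .escape_field(e$text)
    ),
    source = coalesce(e$source, "structured"), ord = 1L
  )
  all <- bind_rows(plines, elines) |>
    arrange(.data$patient_id, .data$ord) |> select(-"ord")
  lines <- c(.events_header,
             do.call(paste, c(as.list(all), sep = "\t")))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a cohort from the line-delimited event file format
#'
#' Parses the format written by [write_events()]. Parse failures (wrong field
#' count, unparseable date, unknown kind) raise an error naming the offending
#' line number; record-level rule violations (unknown parameter, negative
#' value, event predating birth) raise a validation error.
#'
#' @param path Path to an event file.
#' @param validate If `TRUE` (default), run [validate_events()] and fail on
#'   violations.
#' @return A [clivd_cohort()].
#' @export
read_events <- function(path, validate = TRUE) {
  if (!file.exists(path)) abort(paste0("file does not exist: ", path))
  lines <- readr::read_lines(path)
  if (length(lines) == 0 || lines[[1]] != .events_header) {
    abort("line 1: expected event-file header")
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(clivd_cohort(
      tibble(patient_id = character(), sex = character(),
             birth_date = as.Date(character()))))
  }
  # a sentinel preserves trailing empty fields, which strsplit() drops
  fields <- lapply(strsplit(paste0(body, "\t."), "\t", fixed = TRUE),
                   function(x) x[-length(x)])
  nf <- lengths(fields)
  if (any(nf != 6L)) {
    bad <- which(nf != 6L)[1]
    abort(sprintf("line %d: expected 6 tab-separated fields, found %d",
                  bad + 1L, nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 6, byrow = TRUE)
  rec <- tibble(
    line = seq_along(body) + 1L,
    patient_id = m[, 1], date_chr = m[, 2], kind = m[, 3],
    detail = m[, 4], value = m[, 5], source = m[, 6]
  )
  rec$date <- as.Date(rec$date_chr, format = "%Y-%m-%d")
  if (anyNA(rec$date)) {
    bad <- rec$line[is.na(rec$date)][1]
    abort(sprintf("line %d: unparseable date", bad))
  }
  bad_kind <- !rec$kind %in% c("patient", "measurement", "diagnosis", "text")
  if (any(bad_kind)) {
    abort(sprintf("line %d: unknown record kind '%s'",
                  rec$line[bad_kind][1], rec$kind[bad_kind][1]))
  }

  prec <- rec[rec$kind == "patient", ]
  if (anyDuplicated(prec$patient_id)) {
    dup <- prec$patient_id[duplicated(prec$patient_id)][1]
    abort(sprintf("duplicate patient record for id '%s'", dup))
  }
  patients <- tibble(patient_id = prec$patient_id, sex = prec$detail,
                     birth_date = prec$date)

  erec <- rec[rec$kind != "patient", ]
  mm <- erec$kind == "measurement"
  unknown <- mm & !erec$detail %in% names(.clivd_parameters)
  if (any(unknown)) {
    abort(sprintf("line %d: unknown measurement parameter '%s'",
                  erec$line[unknown][1], erec$detail[unknown][1]))
  }
  val <- rep(NA_real_, nrow(erec))
  smk <- mm & erec$detail == "smoking_status"
  val[smk] <- as.numeric(erec$value[smk] == "true")
  num <- mm & !smk
  suppressWarnings(val[num] <- as.numeric(erec$value[num]))
  if (any(num & is.na(val))) {
    bad <- erec$line[num & is.na(val)][1]
    abort(sprintf("line %d: unparseable measurement value", bad))
  }
  events <- tibble(
    patient_id = erec$patient_id, date = erec$date, kind = erec$kind,
    parameter = ifelse(mm, erec$detail, NA_character_),
    value = val,
    system = ifelse(erec$kind == "diagnosis", erec$detail, NA_character_),
    code = ifelse(erec$kind == "diagnosis", erec$value, NA_character_),
    text = ifelse(erec$kind == "text", .unescape_field(erec$value), NA_character_),
    source = ifelse(nzchar(erec$source), erec$source, "structured")
  )
  clivd_cohort(patients, events, validate = validate)
}

#' Subset a cohort to one patient (an event stream)
#'
#' @param cohort A [clivd_cohort()].
#' @param patient_id A patient id present in the cohort.
#' @return A single-patient `clivd_cohort`.
#' @export
event_stream <- function(cohort, patient_id) {
  if (!patient_id %in% cohort$patients$patient_id) {
    abort(sprintf("no patient '%s' in cohort", patient_id))
  }
  clivd_cohort(
    cohort$patients[cohort$patients$patient_id == patient_id, ],
    cohort$events[cohort$events$patient_id == patient_id, ],
    validate = FALSE
  )
}
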