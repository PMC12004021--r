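#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% .data abort warn
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm rbinom rpois runif setNames var
#' @importFrom utils head tail
NULL

.clivd_sexes <- c("male", "female")

# structured measurement parameters and their units
.clivd_parameters <- c(
  fasting_glucose          = "mmol/L",
  height                   = "cm",
  weight                   = "kg",
  bmi                      = "kg/m2",
  waist_circumference      = "cm",
  hip_circumference        = "cm",
  ggt                      = "U/L",
  whr                      = "ratio",
  smoking_status           = "boolean",
  alcohol_servings_per_week = "servings/week"
)

.clivd_whr_range <- c(0.3, 2.0)

#' Age in whole years at a date
#'
#' Whole calendar years elapsed between `birth_date` and `date` (the usual
#' "age at last birthday").
#'
#' @param birth_date,date `Date` vectors (recycled).
#' @return Integer vector of ages.
#' @export
#' @examples
#' age_at(as.Date("1970-06-15"), as.Date("2020-06-14"))  # 49
#' age_at(as.Date("1970-06-15"), as.Date("2020-06-15"))  # 50
age_at <- function(birth_date, date) {
  b <- as.POSIXlt(birth_date)
  d <- as.POSIXlt(date)
  age <- d$year - b$year
  before_birthday <- (d$mon < b$mon) | (d$mon == b$mon & d$mday < b$mday)
  as.integer(age - before_birthday)
}

# deterministic double formatting used by the event file writer (15 significant
# digits; values the generator emits are rounded well below this)
.fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- NA_character_
  out
}

.is_date <- function(x) inherits(x, "Date")

.assert_date_scalar <- function(x, arg = "date") {
  if (!.is_date(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing Date.", arg))
  }
  invisible(x)
}

# ICD-10: letter + 2 digits, optional dotted subcode ("F10.20", "K70", "C22.0")
.icd10_rx <- "^[A-Z][0-9]{2}(\\.[0-9]{1,2})?$"
# ICPC-2: letter + 2 digits ("P15")
.icpc2_rx <- "^[A-Z][0-9]{2}$"

.code_syntax_ok <- function(system, code) {
  ok <- rep(FALSE, length(code))
  icd <- system == "ICD-10"
  ok[icd] <- grepl(.icd10_rx, code[icd])
  ok[!icd] <- grepl(.icpc2_rx, code[!icd])
  ok
}

# family-prefix diagnosis code matching: a pattern like "F10.2X" (trailing
# X's are wildcards) or "K70" matches any code in that family.
code_matches <- function(code, pattern) {
  prefix <- sub("X+$", "", pattern)
  startsWith(code, prefix)
}
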