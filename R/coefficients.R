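.required_coefs <- list(
  nonlab = c("male", "age_per_year", "smoker", "alcohol_per_serving_week",
             "whr_per_unit", "diabetes"),
  lab = c("male", "age_per_year", "smoker", "alcohol_per_serving_week",
          "whr_per_unit", "diabetes", "log_ggt")
)

#' Load a CLivD coefficient file
#'
#' Coefficients ship as a structured text (YAML) transcription file rather
#' than being hard-coded, so the transcription is auditable and replaceable.
#' The packaged default, `clivd_coefficients_synthetic.yaml`, is a clearly
#' labelled synthetic stand-in: it reproduces the functional form, input set
#' and coefficient signs of the published CLivD model, with package-chosen
#' numeric values (see the file header and the methods vignette). Loading
#' fails unless every coefficient required by a variant is present and finite.
#'
#' @param path Path to a coefficient YAML file; `NULL` loads the packaged
#'   synthetic stand-in.
#' @return A `clivd_coefficients` object: variants `lab` and `nonlab`, each
#'   with `baseline_survival`, `centering` and `coefficients`; plus `cutoffs`,
#'   `age_window` and a `provenance` note.
#' @export
clivd_coefficients <- function(path = NULL) {
  path <- path %||% system.file("extdata", "clivd_coefficients_synthetic.yaml",
                                package = "clivdr")
  if (!file.exists(path)) abort(paste0("coefficient file not found: ", path))
  raw <- yaml::read_yaml(path)
  for (v in c("nonlab", "lab")) {
    blk <- raw$variants[[v]]
    if (is.null(blk)) abort(sprintf("coefficient file lacks variant '%s'", v))
    missing <- setdiff(.required_coefs[[v]], names(blk$coefficients))
    if (length(missing) > 0) {
      abort(sprintf("variant '%s' lacks coefficients: %s",
                    v, paste(missing, collapse = ", ")))
    }
    vals <- unlist(blk$coefficients)
    if (any(!is.finite(vals))) abort(sprintf("variant '%s' has non-finite coefficients", v))
    s0 <- blk$baseline_survival
    if (is.null(s0) || !is.finite(s0) || s0 <= 0 || s0 >= 1) {
      abort(sprintf("variant '%s' needs baseline_survival in (0, 1)", v))
    }
  }
  cut <- c(low = raw$cutoffs$low %||% 0.05, high = raw$cutoffs$high %||% 0.10)
  if (cut["low"] >= cut["high"]) abort("cutoffs must satisfy low < high")
  structure(
    list(variants = raw$variants,
         cutoffs = cut,
         age_window = c(raw$age_window$min %||% 40, raw$age_window$max %||% 70),
         provenance = raw$provenance %||% "unspecified",
         path = path),
    class = "clivd_coefficients"
  )
}

#' @export
print.clivd_coefficients <- function(x, ...) {
  cat("<clivd_coefficients>\n")
  cat("  variants: ", paste(names(x$variants), collapse = ", "), "\n", sep = "")
  cat(sprintf("  cutoffs: low %.0f%%, high %.0f%%\n",
              100 * x$cutoffs["low"], 100 * x$cutoffs["high"]))
  cat(sprintf("  age window: %d-%d\n", x$age_window[1], x$age_window[2]))
  cat("  provenance: ", trimws(x$provenance), "\n", sep = "")
  invisible(x)
}

#' CLivD 10-year risk score
#'
#' Evaluates the CLivD risk function: a linear predictor over sex, age,
#' current smoking, weekly alcohol servings, waist-hip ratio and diabetes
#' (plus log GGT for the `lab` variant), mapped to a 10-year probability via
#' the baseline survival: `risk = 1 - S0 ^ exp(lp)`. Deterministic and
#' vectorised; the `nonlab` variant ignores `ggt`.
#'
#' @param inputs Data frame with columns `sex`, `age`, `smoking` (logical or
#'   0/1), `alcohol` (servings/week), `whr`, `diabetes` (logical or 0/1) and,
#'   for the lab variant, `ggt` (U/L).
#' @param coefficients A [clivd_coefficients()] object.
#' @param variant `"nonlab"` or `"lab"`, recycled over rows; a per-row
#'   `variant` column in `inputs` takes precedence.
#' @return Numeric vector of 10-year risks in `[0, 1]`.
#' @export
#' @examples
#' co <- clivd_coefficients()
#' clivd_score(data.frame(sex = "male", age = 55, smoking = TRUE,
#'                        alcohol = 20, whr = 1.0, diabetes = TRUE), co)
clivd_score <- function(inputs, coefficients = clivd_coefficients(),
                        variant = "nonlab") {
  inputs <- as_tibble(inputs)
  if ("variant" %in% names(inputs)) variant <- inputs$variant
  variant <- rep(variant, length.out = nrow(inputs))
  if (any(!variant %in% c("lab", "nonlab"))) {
    abort("unknown model variant; must be 'lab' or 'nonlab'")
  }
  req <- c("sex", "age", "smoking", "alcohol", "whr", "diabetes")
  miss <- setdiff(req, names(inputs))
  if (length(miss) > 0) {
    abort(paste0("inputs lack required columns: ", paste(miss, collapse = ", ")))
  }
  need_ggt <- variant == "lab"
  if (any(need_ggt) && (!"ggt" %in% names(inputs) || anyNA(inputs$ggt[need_ggt]))) {
    abort("lab variant requires a non-missing ggt input")
  }
  core <- inputs[, req]
  if (anyNA(core)) abort("inputs contain missing values for required parameters")
  if (any(!inputs$sex %in% .clivd_sexes)) abort("sex must be 'male' or 'female'")

  risk <- numeric(nrow(inputs))
  for (v in unique(variant)) {
    idx <- variant == v
    blk <- coefficients$variants[[v]]
    b <- blk$coefficients
    ctr <- blk$centering
    lp <- b$male * (inputs$sex[idx] == "male") +
      b$age_per_year * (inputs$age[idx] - (ctr$age %||% 0)) +
      b$smoker * as.numeric(inputs$smoking[idx]) +
      b$alcohol_per_serving_week * inputs$alcohol[idx] +
      b$whr_per_unit * (inputs$whr[idx] - (ctr$whr %||% 0)) +
      b$diabetes * as.numeric(inputs$diabetes[idx])
    if (v == "lab") {
      lp <- lp + b$log_ggt * (log(inputs$ggt[idx]) - (ctr$log_ggt %||% 0))
    }
    risk[idx] <- 1 - blk$baseline_survival^exp(lp)
  }
  pmin(pmax(risk, 0), 1)
}
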