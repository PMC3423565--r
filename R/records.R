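#' @importFrom rlang .data
NULL

#' Etiology codes for acute liver failure
#'
#' The 2002 etiology taxonomy (as modified in 2011) assigns each patient one
#' of ten major etiology classes; viral infections and drug-induced injuries
#' carry a sub-classification. Etiologies I (viral), II (autoimmune), and
#' III with the allergy sub-type define the histological-hepatitis group:
#' such patients are diagnosed as having fulminant hepatitis as well as ALF,
#' while III-toxicity and IV-VIII are ALF only.
#'
#' @return `etiology_codes()`: character vector of the ten major codes.
#'   `etiology_subcodes()`: named list of permitted sub-codes for the majors
#'   that have them.
#' @export
etiology_codes <- function() {
  c("I_viral", "II_autoimmune", "III_drug", "IV_circulatory",
    "V_malignant_infiltration", "VI_metabolic",
    "VII_post_resection_transplant", "VIII_miscellaneous",
    "IX_indeterminate", "X_unclassified")
}

#' @rdname etiology_codes
#' @export
etiology_subcodes <- function() {
  list(
    I_viral = c("HAV", "HBV_transient", "HBV_carrier_inactive",
                "HBV_reactivation_carrier", "HBV_de_novo",
                "HBV_indeterminate", "HCV", "HEV", "other"),
    III_drug = c("allergy", "toxicity")
  )
}

treatment_levels <- function() c("medical_only", "transplant")

outcome_levels <- function() {
  c("survived", "died", "transplanted_alive", "transplanted_dead")
}

# Canonical column order of a patient-record tibble.
record_columns <- function() {
  c("patient_id", "age_years", "is_pediatric",
    "onset_to_encephalopathy_days", "onset_to_labs_weeks",
    "pt_percent", "inr", "total_bilirubin", "direct_bilirubin", "dt_ratio",
    "platelets", "liver_atrophy", "coma_grade",
    "etiology", "etiology_sub",
    "prior_liver_function_normal", "habitual_alcohol_as_cause",
    "treatment", "outcome")
}

record_col_spec <- function() {
  readr::cols(
    patient_id = readr::col_character(),
    age_years = readr::col_integer(),
    is_pediatric = readr::col_logical(),
    onset_to_encephalopathy_days = readr::col_integer(),
    onset_to_labs_weeks = readr::col_double(),
    pt_percent = readr::col_double(),
    inr = readr::col_double(),
    total_bilirubin = readr::col_double(),
    direct_bilirubin = readr::col_double(),
    dt_ratio = readr::col_double(),
    platelets = readr::col_double(),
    liver_atrophy = readr::col_logical(),
    coma_grade = readr::col_character(),
    etiology = readr::col_character(),
    etiology_sub = readr::col_character(),
    prior_liver_function_normal = readr::col_logical(),
    habitual_alcohol_as_cause = readr::col_logical(),
    treatment = readr::col_character(),
    outcome = readr::col_character()
  )
}

#' Read patient records from CSV or JSON
#'
#' Reads a table of one row per patient (see the README for the column
#' dictionary), validates every row against the record invariants, and
#' derives the direct/total bilirubin ratio where both bilirubins are
#' present. Missing values are empty cells in CSV and `null` in JSON; no
#' imputation is ever performed.
#'
#' @param path path to the file.
#' @param format `"auto"` (by extension), `"csv"`, or `"json"`.
#' @return a validated tibble of patient records with `coma_grade` as an
#'   ordered factor and `dt_ratio` filled in.
#' @export
#' @examples
#' path <- system.file("extdata", "survey2010_strata.csv", package = "alftriage")
#' # record files use read_records(); the stratum fixture has its own loader:
#' survey_strata()
read_records <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) {
    abort_alf(sprintf("file not found: %s", path), class = "alf_io_error")
  }
  raw <- if (format == "csv") {
    out <- tryCatch(
      readr::read_csv(path, col_types = record_col_spec(), na = c("", "NA")),
      error = function(e) abort_alf(
        sprintf("cannot parse %s as CSV: %s", path, conditionMessage(e)),
        class = "alf_parse_error")
    )
    probs <- readr::problems(out)
    if (nrow(probs) > 0) {
      abort_alf(
        sprintf("malformed CSV %s at line %d: %s", path,
                probs$row[1] + 1L, probs$expected[1]),
        class = "alf_parse_error"
      )
    }
    out
  } else {
    parsed <- tryCatch(
      jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
      error = function(e) abort_alf(
        sprintf("cannot parse %s as JSON: %s", path, conditionMessage(e)),
        class = "alf_parse_error")
    )
    tibble::as_tibble(parsed)
  }
  validate_records(raw)
}

#' Write patient records to CSV or JSON
#'
#' Inverse of [read_records()]: writing then re-reading a valid record table
#' reproduces it exactly. Missing values become empty cells (CSV) or `null`
#' (JSON).
#'
#' @param records a validated patient-record tibble.
#' @param path output path.
#' @param format `"auto"` (by extension), `"csv"`, or `"json"`.
#' @return `records`, invisibly.
#' @export
write_records <- function(records, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  out <- validate_records(records)
  out$coma_grade <- as.character(out$coma_grade)
  if (format == "csv") {
    readr::write_csv(out, path, na = "")
  } else {
    jsonlite::write_json(out, path, na = "null", auto_unbox = FALSE,
                         digits = NA, pretty = TRUE)
  }
  invisible(records)
}

#' Validate a patient-record table
#'
#' Checks every row against the record schema: lab ranges, the
#' direct-less-than-total bilirubin constraint, presence of at least one of
#' PT% and INR, the coma-grade/interval linkage (the onset-to-encephalopathy
#' interval must be present exactly when the coma grade is II or worse), and
#' the etiology taxonomy. All row-level violations are collected and
#' reported together with patient ids.
#'
#' @param records data frame of patient records; missing columns other than
#'   `patient_id` and the labs are tolerated and filled with NA.
#' @return the validated tibble, with `dt_ratio` derived where both
#'   bilirubins are present (`NA` when total bilirubin is zero) and
#'   `coma_grade` as an ordered factor.
#' @export
validate_records <- function(records) {
  assert_data_frame(records)
  x <- tibble::as_tibble(records)
  if (!"patient_id" %in% names(x)) {
    abort_alf("`records` lacks required column: patient_id",
              class = "alf_validation_error")
  }
  for (col in setdiff(record_columns(), names(x))) {
    x[[col]] <- switch(
      col,
      age_years = NA_integer_,
      onset_to_encephalopathy_days = NA_integer_,
      is_pediatric = NA,
      liver_atrophy = NA,
      prior_liver_function_normal = NA,
      habitual_alcohol_as_cause = NA,
      NA_real_
    )
    if (col %in% c("coma_grade", "etiology", "etiology_sub",
                   "treatment", "outcome")) {
      x[[col]] <- NA_character_
    }
  }
  x <- x[c(record_columns(), setdiff(names(x), record_columns()))]
  x$patient_id <- as.character(x$patient_id)

  # dt_ratio: derive whenever both bilirubins are present; undefined at TB = 0
  derivable <- !is.na(x$total_bilirubin) & !is.na(x$direct_bilirubin)
  x$dt_ratio <- ifelse(derivable & x$total_bilirubin > 0,
                       x$direct_bilirubin / x$total_bilirubin,
                       ifelse(derivable, NA_real_, x$dt_ratio))

  problems <- character(0)
  flag <- function(bad, msg) {
    bad <- which(!is.na(bad) & bad)
    if (length(bad)) {
      ids <- x$patient_id[bad]
      problems <<- c(problems,
                     sprintf("row %d (patient %s): %s", bad, ids, msg))
    }
  }

  flag(x$age_years < 0, "age_years must be >= 0")
  flag(x$pt_percent < 0 | x$pt_percent > 150,
       "pt_percent must be in [0, 150]")
  flag(x$inr <= 0, "inr must be > 0")
  flag(x$total_bilirubin < 0, "total_bilirubin must be >= 0")
  flag(x$direct_bilirubin < 0, "direct_bilirubin must be >= 0")
  flag(x$platelets < 0, "platelets must be >= 0")
  flag(x$onset_to_encephalopathy_days < 0,
       "onset_to_encephalopathy_days must be >= 0")
  flag(x$onset_to_labs_weeks < 0, "onset_to_labs_weeks must be >= 0")
  flag(!is.na(x$total_bilirubin) & !is.na(x$direct_bilirubin) &
         x$direct_bilirubin > x$total_bilirubin,
       "direct>total: direct_bilirubin exceeds total_bilirubin")
  flag(is.na(x$pt_percent) & is.na(x$inr),
       "at least one of pt_percent and inr is required")
  flag(!is.na(x$coma_grade) & !x$coma_grade %in% coma_levels(),
       sprintf("coma_grade must be one of %s",
               paste(coma_levels(), collapse = ", ")))
  flag(!is.na(x$etiology) & !x$etiology %in% etiology_codes(),
       "unknown etiology code")
  subs <- etiology_subcodes()
  flag(!is.na(x$etiology_sub) &
         (is.na(x$etiology) | !x$etiology %in% names(subs)),
       "etiology_sub only permitted for I_viral and III_drug")
  for (major in names(subs)) {
    flag(!is.na(x$etiology_sub) & !is.na(x$etiology) & x$etiology == major &
           !x$etiology_sub %in% subs[[major]],
         sprintf("invalid etiology_sub for %s", major))
  }
  flag(!is.na(x$treatment) & !x$treatment %in% treatment_levels(),
       "treatment must be medical_only or transplant")
  flag(!is.na(x$outcome) & !x$outcome %in% outcome_levels(),
       sprintf("outcome must be one of %s",
               paste(outcome_levels(), collapse = ", ")))

  # interval present iff encephalopathy reached grade II or worse
  known_grade <- !is.na(x$coma_grade) & x$coma_grade %in% coma_levels()
  grade_ge2 <- known_grade &
    match(x$coma_grade, coma_levels()) - 1L >= 2L
  flag(grade_ge2 & is.na(x$onset_to_encephalopathy_days),
       "onset_to_encephalopathy_days required when coma grade is II or worse")
  flag(known_grade & !grade_ge2 & !is.na(x$onset_to_encephalopathy_days),
       "onset_to_encephalopathy_days must be absent when coma grade is below II")

  if (length(problems)) {
    abort_alf(
      paste(c(sprintf("%d invalid record(s):", length(problems)),
              utils::head(problems, 20)), collapse = "\n"),
      class = "alf_validation_error",
      problems = problems
    )
  }
  x$coma_grade <- coma_grade(x$coma_grade)
  x
}
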