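#' Severe-liver-damage laboratory criterion
#'
#' The 2011 diagnostic criteria define severe liver damage as a prothrombin
#' time of 40 % or less of the standardized value, or an INR of 1.5 or more.
#' Either measurement suffices; a record with both missing cannot be
#' classified.
#'
#' @param pt_percent prothrombin time, percent of the standardized value
#'   (NA allowed).
#' @param inr international normalized ratio (NA allowed).
#' @param config an [alf_config()] (cut points `pt_max_percent`, `inr_min`).
#' @return logical vector: `TRUE` where the criterion is met.
#' @export
#' @examples
#' meets_lab_criterion(pt_percent = 40, inr = NA)  # TRUE (boundary inclusive)
#' meets_lab_criterion(pt_percent = 41, inr = 1.5) # TRUE via INR
#' meets_lab_criterion(pt_percent = 80, inr = 1.0) # FALSE
meets_lab_criterion <- function(pt_percent, inr, config = alf_config()) {
  n <- max(length(pt_percent), length(inr))
  pt_percent <- rep_len(pt_percent, n)
  inr <- rep_len(inr, n)
  if (any(is.na(pt_percent) & is.na(inr))) {
    abort_missing("lab criterion needs at least one of pt_percent and inr")
  }
  (!is.na(pt_percent) & pt_percent <= config$pt_max_percent) |
    (!is.na(inr) & inr >= config$inr_min)
}

diagnosis_categories <- function() {
  c("NOT_ALF", "ALF_WITHOUT_COMA", "ALF_WITH_COMA_ACUTE",
    "ALF_WITH_COMA_SUBACUTE", "LOHF")
}

#' Fulminant-hepatitis compatibility of an etiology
#'
#' Among patients with acute liver failure or LOHF, those whose etiology
#' implies histological hepatitis — viral infection (I), autoimmune
#' hepatitis (II), or drug *allergy*-induced injury (III-1) — are diagnosed
#' as having fulminant hepatitis as well; drug toxicity (III-2) and
#' etiologies IV-VIII are ALF only. Indeterminate etiology (IX) counts as
#' hepatitis-compatible by default (the nationwide survey tallies it within
#' the hepatitis group); unclassified (X) does not. Both policies are
#' configurable.
#'
#' @param category diagnosis category (any value of
#'   `diagnosis_categories()`); `NOT_ALF` always yields `FALSE`.
#' @param etiology major etiology code, see [etiology_codes()].
#' @param etiology_sub sub-code (`"allergy"`/`"toxicity"` for III, viral
#'   sub-types for I); only consulted for `III_drug`.
#' @param config an [alf_config()].
#' @return logical vector.
#' @export
is_fulminant_hepatitis <- function(category, etiology, etiology_sub = NA,
                                   config = alf_config()) {
  n <- max(length(category), length(etiology), length(etiology_sub))
  category <- rep_len(category, n)
  etiology <- rep_len(etiology, n)
  etiology_sub <- rep_len(etiology_sub, n)
  out <- rep(FALSE, n)
  known <- !is.na(etiology)
  out[known & etiology %in% c("I_viral", "II_autoimmune")] <- TRUE
  out[known & etiology == "III_drug" &
        !is.na(etiology_sub) & etiology_sub == "allergy"] <- TRUE
  out[known & etiology == "IX_indeterminate"] <- isTRUE(config$indeterminate_fulminant)
  out[known & etiology == "X_unclassified"] <- isTRUE(config$unclassified_fulminant)
  out[!is.na(category) & category == "NOT_ALF"] <- FALSE
  out
}

#' Classify patient records under the 2011 ALF criteria
#'
#' Applies the 2011 Japanese diagnostic criteria to each record:
#'
#' 1. The laboratory criterion ([meets_lab_criterion()]) must be met;
#'    otherwise the record is `NOT_ALF` (`lab_criterion_not_met`).
#' 2. Liver function before the current injury must have been normal
#'    (`prior_liver_function_normal`); otherwise `NOT_ALF`
#'    (`prior_liver_disease`). Alcoholic hepatitis
#'    (`habitual_alcohol_as_cause`) is excluded (`alcoholic_hepatitis`).
#' 3. With no or grade-I encephalopathy, qualifying labs within 8 weeks of
#'    symptom onset give `ALF_WITHOUT_COMA`; later labs are `NOT_ALF`
#'    (`window_exceeded`).
#' 4. With grade-II-or-worse encephalopathy, the onset-to-encephalopathy
#'    interval decides the type: within 10 days `ALF_WITH_COMA_ACUTE`,
#'    11-56 days `ALF_WITH_COMA_SUBACUTE`, 57-168 days (8-24 weeks) `LOHF`,
#'    beyond 168 days `NOT_ALF` (`window_exceeded`).
#'
#' The fulminant-hepatitis flag is then attached via
#' [is_fulminant_hepatitis()]. Intervals are inclusive day counts from the
#' calendar day of first symptoms.
#'
#' @param records a patient-record data frame (validated with
#'   [validate_records()]; `coma_grade` must be resolvable — grade feature
#'   flags can be converted first with [grade_coma()]).
#' @param config an [alf_config()] with the boundary values.
#' @return the input tibble with columns `category` (factor over
#'   `diagnosis_categories()`), `fulminant_hepatitis` (logical),
#'   `exclusion_reason` (NA unless `NOT_ALF`), and `rationale`
#'   (semicolon-separated applied-rule identifiers) appended.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   patient_id = "p1", pt_percent = 30, coma_grade = "II",
#'   onset_to_encephalopathy_days = 8L, etiology = "I_viral",
#'   etiology_sub = "HBV_transient",
#'   prior_liver_function_normal = TRUE, habitual_alcohol_as_cause = FALSE
#' )
#' classify_alf(rec)$category  # ALF_WITH_COMA_ACUTE
classify_alf <- function(records, config = alf_config()) {
  x <- validate_records(records)
  n <- nrow(x)
  category <- character(n)
  reason <- rep(NA_character_, n)
  rationale <- vector("list", n)

  lab_ok <- (!is.na(x$pt_percent) & x$pt_percent <= config$pt_max_percent) |
    (!is.na(x$inr) & x$inr >= config$inr_min)
  rank <- coma_rank(x$coma_grade)

  for (i in seq_len(n)) {
    notes <- character(0)
    if (is.na(x$pt_percent[i]) && is.na(x$inr[i])) {
      abort_missing(sprintf(
        "patient %s: both pt_percent and inr missing", x$patient_id[i]))
    }
    if (!lab_ok[i]) {
      category[i] <- "NOT_ALF"
      reason[i] <- "lab_criterion_not_met"
      rationale[[i]] <- "lab_criterion_not_met"
      next
    }
    notes <- c(notes, sprintf("lab_criterion_met(pt<=%s|inr>=%s)",
                              config$pt_max_percent, config$inr_min))
    if (isTRUE(x$habitual_alcohol_as_cause[i])) {
      category[i] <- "NOT_ALF"
      reason[i] <- "alcoholic_hepatitis"
      rationale[[i]] <- c(notes, "excluded:alcoholic_hepatitis")
      next
    }
    if (isFALSE(x$prior_liver_function_normal[i])) {
      category[i] <- "NOT_ALF"
      reason[i] <- "prior_liver_disease"
      rationale[[i]] <- c(notes, "excluded:prior_liver_disease")
      next
    }
    if (is.na(rank[i])) {
      abort_missing(sprintf(
        "patient %s: coma_grade missing and not derivable", x$patient_id[i]))
    }
    if (rank[i] <= 1L) {
      if (is.na(x$onset_to_labs_weeks[i])) {
        abort_missing(sprintf(
          "patient %s: onset_to_labs_weeks required when coma grade is below II",
          x$patient_id[i]))
      }
      if (x$onset_to_labs_weeks[i] <= config$labs_max_weeks) {
        category[i] <- "ALF_WITHOUT_COMA"
        rationale[[i]] <- c(notes, sprintf("coma<II & labs within %s weeks",
                                           config$labs_max_weeks))
      } else {
        category[i] <- "NOT_ALF"
        reason[i] <- "window_exceeded"
        rationale[[i]] <- c(notes, "excluded:labs_after_8_weeks")
      }
      next
    }
    interval <- x$onset_to_encephalopathy_days[i]
    if (is.na(interval)) {
      abort_missing(sprintf(
        "patient %s: onset_to_encephalopathy_days required for coma grade >= II",
        x$patient_id[i]))
    }
    if (interval <= config$acute_max_days) {
      category[i] <- "ALF_WITH_COMA_ACUTE"
      rationale[[i]] <- c(notes, sprintf("coma>=II within %d days",
                                         config$acute_max_days))
    } else if (interval <= config$subacute_max_days) {
      category[i] <- "ALF_WITH_COMA_SUBACUTE"
      rationale[[i]] <- c(notes, sprintf("coma>=II in %d-%d days",
                                         config$acute_max_days + 1L,
                                         config$subacute_max_days))
    } else if (interval <= config$lohf_max_days) {
      category[i] <- "LOHF"
      rationale[[i]] <- c(notes, sprintf("coma>=II in %d-%d days",
                                         config$subacute_max_days + 1L,
                                         config$lohf_max_days))
    } else {
      category[i] <- "NOT_ALF"
      reason[i] <- "window_exceeded"
      rationale[[i]] <- c(notes, sprintf("excluded:coma_after_%d_days",
                                         config$lohf_max_days))
    }
  }

  fh <- is_fulminant_hepatitis(category, x$etiology, x$etiology_sub, config)
  dplyr::mutate(
    x,
    category = factor(category, levels = diagnosis_categories()),
    fulminant_hepatitis = fh,
    exclusion_reason = reason,
    rationale = purrr::map_chr(rationale, paste, collapse = "; ")
  )
}
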