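#' Initial transplant-candidacy assessment (1996 guideline, step 1)
#'
#' At the onset of grade-II-or-worse hepatic encephalopathy, five
#' poor-prognosis criteria are evaluated:
#'
#' 1. age 45 years or older;
#' 2. interval from initial symptoms to encephalopathy of 11 days or more;
#' 3. prothrombin time below 10 % of the standardized value;
#' 4. serum total bilirubin of 18.0 mg/dL or more;
#' 5. direct/total bilirubin ratio below 0.67.
#'
#' A patient satisfying at least 2 of the 5 is given an estimated prognosis
#' of "death" and registered as a transplant candidate. Boundary strictness
#' follows the guideline exactly and intentionally differs from the 2011
#' scoring-system cut points.
#'
#' @param records patient-record data frame with `age_years`,
#'   `onset_to_encephalopathy_days`, `pt_percent`, `total_bilirubin`,
#'   `direct_bilirubin` (or `dt_ratio`), and `coma_grade` (must be II or
#'   worse).
#' @return the input tibble with logical columns `crit_age`,
#'   `crit_interval`, `crit_pt`, `crit_bilirubin`, `crit_dt_ratio`, plus
#'   `n_met` (0-5) and `candidate` appended.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   patient_id = "p1", age_years = 50L, coma_grade = "II",
#'   onset_to_encephalopathy_days = 12L, pt_percent = 30,
#'   total_bilirubin = 10, direct_bilirubin = 8
#' )
#' assess_transplant_criteria(rec)[, c("n_met", "candidate")]
assess_transplant_criteria <- function(records) {
  x <- validate_records(records)
  rank <- coma_rank(x$coma_grade)
  if (any(is.na(rank) | rank < 2L)) {
    bad <- x$patient_id[is.na(rank) | rank < 2L]
    abort_alf(
      sprintf(paste0("transplant candidacy is assessed at the onset of grade ",
                     "II or more severe encephalopathy; not met for ",
                     "patient(s): %s"), paste(bad, collapse = ", ")),
      class = "alf_precondition_error"
    )
  }
  needed <- list(age_years = x$age_years,
                 onset_to_encephalopathy_days = x$onset_to_encephalopathy_days,
                 pt_percent = x$pt_percent,
                 total_bilirubin = x$total_bilirubin,
                 dt_ratio = x$dt_ratio)
  for (nm in names(needed)) {
    if (any(is.na(needed[[nm]]))) {
      abort_missing(sprintf(
        "patient %s: `%s` required for transplant-candidacy assessment",
        x$patient_id[which(is.na(needed[[nm]]))[1]], nm))
    }
  }
  dplyr::mutate(
    x,
    crit_age = .data$age_years >= 45,
    crit_interval = .data$onset_to_encephalopathy_days >= 11,
    crit_pt = .data$pt_percent < 10,
    crit_bilirubin = .data$total_bilirubin >= 18.0,
    crit_dt_ratio = .data$dt_ratio < 0.67,
    n_met = .data$crit_age + .data$crit_interval + .data$crit_pt +
      .data$crit_bilirubin + .data$crit_dt_ratio,
    candidate = .data$n_met >= 2
  )
}

#' Day-5 reassessment of transplant candidacy (1996 guideline, step 2)
#'
#' If transplantation cannot be performed within 5 days of encephalopathy
#' onset and intensive medical therapy (artificial liver support) is given,
#' candidates are re-evaluated on day 5. The prognosis is revised to
#' "alive" — and the patient removed from the candidate list — only when
#' *both* hold:
#'
#' 1. the encephalopathy has improved to grade I or less, or attenuated by
#'    2 or more grades from its value at onset;
#' 2. the prothrombin time has improved to over 50 % of the standardized
#'    value.
#'
#' The reassessment can only flip an estimated "death" toward "alive",
#' never the reverse; non-candidates are refused.
#'
#' @param assessment output of [assess_transplant_criteria()]; every row
#'   must have `candidate = TRUE`.
#' @param coma_day5 coma grade on day 5 (character or ordered factor).
#' @param pt_day5 prothrombin time on day 5, percent of standardized value.
#' @param coma_at_onset coma grade at encephalopathy onset; defaults to the
#'   `coma_grade` column of `assessment`.
#' @return `assessment` with logical columns `coma_improved`, `pt_improved`,
#'   `reassessed_alive`, and the revised `candidate_final` appended.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   patient_id = "p1", age_years = 50L, coma_grade = "IV",
#'   onset_to_encephalopathy_days = 12L, pt_percent = 8,
#'   total_bilirubin = 19, direct_bilirubin = 9
#' )
#' a <- assess_transplant_criteria(rec)
#' reassess_day5(a, coma_day5 = "II", pt_day5 = 60)$reassessed_alive  # TRUE
reassess_day5 <- function(assessment, coma_day5, pt_day5,
                          coma_at_onset = assessment$coma_grade) {
  assert_data_frame(assessment)
  assert_columns(assessment, c("candidate", "patient_id"))
  if (any(!assessment$candidate)) {
    abort_alf(
      sprintf("day-5 reassessment applies only to transplant candidates; patient(s): %s",
              paste(assessment$patient_id[!assessment$candidate], collapse = ", ")),
      class = "alf_precondition_error"
    )
  }
  n <- nrow(assessment)
  onset_rank <- coma_rank(rep_len(as.character(coma_at_onset), n))
  day5_rank <- coma_rank(rep_len(as.character(coma_day5), n))
  pt_day5 <- rep_len(pt_day5, n)
  if (any(is.na(day5_rank)) || any(is.na(pt_day5))) {
    abort_missing("coma_day5 and pt_day5 are required for every candidate")
  }
  dplyr::mutate(
    assessment,
    coma_improved = day5_rank <= 1L | (onset_rank - day5_rank) >= 2L,
    pt_improved = pt_day5 > 50,
    reassessed_alive = .data$coma_improved & .data$pt_improved,
    candidate_final = .data$candidate & !.data$reassessed_alive
  )
}
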