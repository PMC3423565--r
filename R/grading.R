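#' Clinical feature flags for coma grading
#'
#' `adult_coma_features()` and `pediatric_coma_features()` return the names
#' of the logical flag columns understood by [grade_coma()] and
#' [grade_coma_pediatric()]. Each flag corresponds to one manifestation in
#' the defining ("psychiatric disorders") column of the respective grading
#' table; the illustrative reference items are deliberately not part of the
#' input, as they overlap across grades.
#'
#' @return character vector of flag names.
#' @export
adult_coma_features <- function() {
  c("sleep_inversion", "euphoria_or_depression", "shortened_attention",
    "disorientation_time_place", "inappropriate_behavior",
    "somnolent_but_responds", "flapping_tremor",
    "excitation_or_delirium", "sleeps_mostly_opens_eyes_to_stimulus",
    "follows_only_simple_orders",
    "complete_loss_of_consciousness", "responds_to_pain",
    "no_response_to_pain")
}

#' @rdname adult_coma_features
#' @export
pediatric_coma_features <- function() {
  c("lethargic_low_spirited", "no_laugh_aloud",
    "obedient_somnolent_or_disoriented", "no_laugh_when_played_with",
    "no_eye_contact_with_mother",
    "opens_eyes_to_loud_voice",
    "no_wake_to_pain_but_grimaces",
    "no_response_to_pain")
}

prepare_features <- function(features, flag_names) {
  assert_data_frame(features)
  x <- tibble::as_tibble(features)
  for (col in setdiff(flag_names, names(x))) x[[col]] <- FALSE
  x <- x[flag_names]
  for (col in flag_names) {
    v <- x[[col]]
    if (!is.logical(v)) {
      abort_alf(sprintf("feature flag `%s` must be logical", col),
                class = "alf_validation_error")
    }
    x[[col]] <- !is.na(v) & v   # absent flag means "not observed"
  }
  x
}

#' Grade hepatic encephalopathy in adults
#'
#' Maps structured clinical-feature flags to the adult ordinal coma grade
#' (Inuyama 1972, grades I-V). Grades are evaluated from V down to I and
#' the highest grade whose defining criterion is satisfied is returned:
#'
#' * **V** — deep coma: complete loss of consciousness with *no* response to
#'   painful stimuli.
#' * **IV** — coma: complete loss of consciousness, but still responds to
#'   painful stimuli.
#' * **III** — any of: excitation and/or delirium; sleeping most of the time
#'   but opening the eyes to stimulation; following only simple orders.
#' * **II** — any of: disorientation of time or place; inappropriate
#'   behaviour; somnolent tendency with appropriate responses; flapping
#'   tremor.
#' * **I** — any of: inverted sleep pattern; euphoria or occasional
#'   depression; shortened attention span.
#' * **none** — no flag set.
#'
#' @param features data frame with one row per patient and logical columns
#'   among [adult_coma_features()]; absent columns are treated as all-FALSE.
#' @return ordered factor of coma grades, one per row.
#' @export
#' @examples
#' grade_coma(data.frame(complete_loss_of_consciousness = TRUE,
#'                       no_response_to_pain = TRUE))   # V
#' grade_coma(data.frame(disorientation_time_place = TRUE,
#'                       flapping_tremor = TRUE))       # II
grade_coma <- function(features) {
  x <- prepare_features(features, adult_coma_features())
  if (any(x$responds_to_pain & x$no_response_to_pain)) {
    abort_alf(
      "responds_to_pain and no_response_to_pain are mutually exclusive",
      class = "alf_validation_error"
    )
  }
  rank <- rep(0L, nrow(x))
  rank[x$sleep_inversion | x$euphoria_or_depression |
         x$shortened_attention] <- 1L
  two <- x$disorientation_time_place | x$inappropriate_behavior |
    x$somnolent_but_responds | x$flapping_tremor
  rank[two] <- 2L
  three <- x$excitation_or_delirium | x$sleeps_mostly_opens_eyes_to_stimulus |
    x$follows_only_simple_orders
  rank[three] <- 3L
  rank[x$complete_loss_of_consciousness & x$responds_to_pain] <- 4L
  rank[x$complete_loss_of_consciousness & x$no_response_to_pain] <- 5L
  coma_grade(coma_levels()[rank + 1L])
}

#' Grade hepatic encephalopathy in children and infants
#'
#' Pediatric counterpart of [grade_coma()] (5th Workshop on Pediatric Liver
#' Diseases, 1988). Grades are evaluated from V down to I:
#'
#' * **V** — no response to painful stimuli.
#' * **IV** — does not wake to painful stimuli but grimaces or brushes the
#'   stimulus away.
#' * **III** — opens eyes only in response to a loud voice.
#' * **II** — obedient attitude with somnolence or disorientation
#'   (children); does not laugh even when played with, or cannot maintain
#'   eye contact with the mother (infants over 3 months).
#' * **I** — low-spirited/lethargic compared with the previous activity
#'   level (children); does not laugh aloud (infants).
#'
#' @param features data frame with one row per patient and logical columns
#'   among [pediatric_coma_features()].
#' @return ordered factor of coma grades, one per row.
#' @export
grade_coma_pediatric <- function(features) {
  x <- prepare_features(features, pediatric_coma_features())
  if (any(x$no_wake_to_pain_but_grimaces & x$no_response_to_pain)) {
    abort_alf(
      "no_wake_to_pain_but_grimaces and no_response_to_pain are mutually exclusive",
      class = "alf_validation_error"
    )
  }
  rank <- rep(0L, nrow(x))
  rank[x$lethargic_low_spirited | x$no_laugh_aloud] <- 1L
  rank[x$obedient_somnolent_or_disoriented | x$no_laugh_when_played_with |
         x$no_eye_contact_with_mother] <- 2L
  rank[x$opens_eyes_to_loud_voice] <- 3L
  rank[x$no_wake_to_pain_but_grimaces] <- 4L
  rank[x$no_response_to_pain] <- 5L
  coma_grade(coma_levels()[rank + 1L])
}
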