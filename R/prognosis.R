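score_parameters <- function() {
  c("oc_days", "pt", "tb", "dt_ratio", "plt", "atrophy")
}

#' Subscore one prognostic parameter
#'
#' The 2011 prognostic scoring system grades six parameters 0/1/2 (liver
#' atrophy 0/1 by default):
#'
#' | parameter  | 0        | 1             | 2       |
#' |------------|----------|---------------|---------|
#' | `oc_days`  | <= 5     | 6-10          | >= 11   |
#' | `pt` (%)   | > 20     | (5, 20]       | <= 5    |
#' | `tb` (mg/dL) | < 10   | \[10, 15)     | >= 15   |
#' | `dt_ratio` | >= 0.7   | \[0.5, 0.7)   | < 0.5   |
#' | `plt` (10^4/uL) | > 10 | (5, 10]      | <= 5    |
#' | `atrophy`  | absent   | present       |         |
#'
#' `oc_days` is the interval between disease onset and the development of
#' grade-II-or-worse hepatic encephalopathy. Missing values are refused,
#' never imputed.
#'
#' @param parameter one of `"oc_days"`, `"pt"`, `"tb"`, `"dt_ratio"`,
#'   `"plt"`, `"atrophy"`.
#' @param value numeric vector (logical for `atrophy`).
#' @param config an [alf_config()]; `atrophy_max_subscore` selects the
#'   subscore for atrophy present (1 by default).
#' @return integer vector of subscores.
#' @export
#' @examples
#' score_component("pt", 20)        # 1 (boundary of the middle bin)
#' score_component("tb", 15)        # 2
#' score_component("dt_ratio", 0.7) # 0
score_component <- function(parameter, value, config = alf_config()) {
  parameter <- match.arg(parameter, score_parameters())
  if (any(is.na(value))) {
    abort_missing(sprintf("missing value for prognostic parameter `%s`",
                          parameter))
  }
  out <- switch(
    parameter,
    oc_days = ifelse(value <= 5, 0L, ifelse(value <= 10, 1L, 2L)),
    pt = ifelse(value > 20, 0L, ifelse(value > 5, 1L, 2L)),
    tb = ifelse(value < 10, 0L, ifelse(value < 15, 1L, 2L)),
    dt_ratio = ifelse(value >= 0.7, 0L, ifelse(value >= 0.5, 1L, 2L)),
    plt = ifelse(value > 10, 0L, ifelse(value > 5, 1L, 2L)),
    atrophy = ifelse(as.logical(value), as.integer(config$atrophy_max_subscore), 0L)
  )
  as.integer(out)
}

#' Predicted-mortality band for a prognostic total score
#'
#' Total scores map to the published predicted-mortality bands: 90-100 %
#' (printed as "greater than 90 %") at a total of 7 or more, 80-90 % at 6,
#' 70-80 % at 5, 50-60 % at 4, and 0-30 % ("less than 30 %") at 3 or less.
#'
#' @param total integer vector of total scores in 0-11.
#' @return tibble with one row per input: `total`, `lower_percent`,
#'   `upper_percent`, `label`.
#' @export
#' @examples
#' mortality_band(c(0, 4, 7))
mortality_band <- function(total) {
  if (any(is.na(total)) || any(total < 0 | total > 11)) {
    abort_alf("total score must be in 0..11", class = "alf_domain_error")
  }
  band_idx <- ifelse(total >= 7, 5L,
              ifelse(total == 6, 4L,
              ifelse(total == 5, 3L,
              ifelse(total == 4, 2L, 1L))))
  bands <- tibble::tibble(
    lower_percent = c(0, 50, 70, 80, 90),
    upper_percent = c(30, 60, 80, 90, 100),
    label = c("<30%", "50-60%", "70-80%", "80-90%", ">90%")
  )
  dplyr::bind_cols(tibble::tibble(total = as.integer(total)),
                   bands[band_idx, ])
}

#' Score records with the 2011 prognostic system
#'
#' Computes the six subscores ([score_component()]), the total score (0-11),
#' the predicted-mortality band ([mortality_band()]), and the death call
#' (predicted death when the total reaches `death_threshold`, 5 by default)
#' for each record. The system is defined for patients with fulminant
#' hepatitis or LOHF, i.e. grade-II-or-worse encephalopathy; records below
#' grade II are refused, as are records missing any of the six parameters
#' (use `allow_partial = TRUE` to instead obtain the attainable score range
#' for incomplete records — an extension beyond the published system,
#' flagged by the `partial` column).
#'
#' @param records patient-record data frame with `onset_to_encephalopathy_days`,
#'   `pt_percent`, `total_bilirubin`, `direct_bilirubin` (or `dt_ratio`),
#'   `platelets`, `liver_atrophy`, and `coma_grade`.
#' @param config an [alf_config()].
#' @param allow_partial if `TRUE`, records with missing parameters are not
#'   refused; their observed subscores are summed into `total_min` and the
#'   missing ones counted at their maximum into `total_max`, with `total`,
#'   `band` and `predicted_death` set to NA.
#' @return the input tibble with columns `score_oc_days`, `score_pt`,
#'   `score_tb`, `score_dt_ratio`, `score_plt`, `score_atrophy`, `total`,
#'   `total_min`, `total_max`, `partial`, `mortality_lower`,
#'   `mortality_upper`, `band`, `predicted_death` appended.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   patient_id = "p1", pt_percent = 4, total_bilirubin = 16,
#'   direct_bilirubin = 6.4, platelets = 4, liver_atrophy = TRUE,
#'   coma_grade = "III", onset_to_encephalopathy_days = 12L
#' )
#' score_prognosis(rec)$total  # 11, the all-maximum case
score_prognosis <- function(records, config = alf_config(),
                            allow_partial = FALSE) {
  x <- validate_records(records)
  rank <- coma_rank(x$coma_grade)
  if (any(is.na(rank) | rank < 2L)) {
    bad <- x$patient_id[is.na(rank) | rank < 2L]
    abort_alf(
      sprintf(paste0("prognostic scoring is defined for grade II or more ",
                     "severe encephalopathy; not met for patient(s): %s"),
              paste(bad, collapse = ", ")),
      class = "alf_precondition_error"
    )
  }

  values <- list(
    oc_days = x$onset_to_encephalopathy_days,
    pt = x$pt_percent,
    tb = x$total_bilirubin,
    dt_ratio = x$dt_ratio,
    plt = x$platelets,
    atrophy = x$liver_atrophy
  )
  max_sub <- c(oc_days = 2L, pt = 2L, tb = 2L, dt_ratio = 2L, plt = 2L,
               atrophy = as.integer(config$atrophy_max_subscore))

  missing_by_row <- purrr::map(values, is.na)
  any_missing <- Reduce(`|`, missing_by_row)
  if (any(any_missing) && !allow_partial) {
    i <- which(any_missing)[1]
    missing_params <- names(values)[purrr::map_lgl(missing_by_row, `[`, i)]
    abort_missing(sprintf(
      "patient %s: missing prognostic parameter(s): %s",
      x$patient_id[i], paste(missing_params, collapse = ", ")))
  }

  subs <- purrr::imap(values, function(v, p) {
    out <- rep(NA_integer_, length(v))
    ok <- !is.na(v)
    if (any(ok)) out[ok] <- score_component(p, v[ok], config)
    out
  })

  observed <- purrr::map(subs, ~ tidyr::replace_na(.x, 0L))
  total_min <- Reduce(`+`, observed)
  total_max <- total_min +
    Reduce(`+`, purrr::imap(missing_by_row,
                            ~ ifelse(.x, max_sub[[.y]], 0L)))
  total <- ifelse(any_missing, NA_integer_, total_min)

  band <- tibble::tibble(lower_percent = rep(NA_real_, nrow(x)),
                         upper_percent = NA_real_, label = NA_character_)
  complete <- !any_missing
  if (any(complete)) band[complete, ] <- mortality_band(total[complete])[-1]

  dplyr::mutate(
    x,
    score_oc_days = subs$oc_days,
    score_pt = subs$pt,
    score_tb = subs$tb,
    score_dt_ratio = subs$dt_ratio,
    score_plt = subs$plt,
    score_atrophy = subs$atrophy,
    total = as.integer(total),
    total_min = as.integer(total_min),
    total_max = as.integer(total_max),
    partial = any_missing,
    mortality_lower = band$lower_percent,
    mortality_upper = band$upper_percent,
    band = band$label,
    predicted_death = total >= config$death_threshold
  )
}
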