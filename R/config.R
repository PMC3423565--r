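#' Thresholds and policy options for the ALF decision stack
#'
#' All cut points used by the classifier, the prognostic score, and the
#' transplant guideline live in this one configuration object. The defaults
#' are the published 2011 values; none of them is hard-coded inside the
#' decision logic, so sensitivity analyses can move a boundary without
#' touching code.
#'
#' @param acute_max_days latest onset-to-encephalopathy interval (days,
#'   inclusive) for the acute type of coma-positive ALF. Default 10.
#' @param subacute_max_days latest interval (days) for the subacute type.
#'   Default 56 (8 weeks).
#' @param lohf_max_days latest interval (days) for late-onset hepatic failure.
#'   Default 168 (24 weeks).
#' @param pt_max_percent prothrombin-time threshold, percent of the
#'   standardized value: the lab criterion is met at PT `<=` this. Default 40.
#' @param inr_min INR threshold: the lab criterion is met at INR `>=` this.
#'   Default 1.5.
#' @param labs_max_weeks latest time of qualifying labs after symptom onset
#'   for ALF without coma (weeks). Default 8.
#' @param death_threshold prognostic total score at or above which the
#'   outcome is called "death". Default 5.
#' @param atrophy_max_subscore subscore assigned to liver atrophy when
#'   present: 1 (default; the published grid prints only two cells for this
#'   row) or 2.
#' @param indeterminate_fulminant should etiology IX (indeterminate despite
#'   sufficient examinations) count as hepatitis-compatible for the
#'   fulminant-hepatitis flag? Default `TRUE` (the survey tallies
#'   indeterminate etiology within the hepatitis group).
#' @param unclassified_fulminant same policy for etiology X (unclassified due
#'   to insufficient examinations). Default `FALSE`.
#' @return a list of class `alf_config`.
#' @seealso [read_alf_config()] to load overrides from a YAML file.
#' @export
#' @examples
#' cfg <- alf_config(death_threshold = 6)
#' cfg$death_threshold
alf_config <- function(acute_max_days = 10,
                       subacute_max_days = 56,
                       lohf_max_days = 168,
                       pt_max_percent = 40,
                       inr_min = 1.5,
                       labs_max_weeks = 8,
                       death_threshold = 5,
                       atrophy_max_subscore = 1,
                       indeterminate_fulminant = TRUE,
                       unclassified_fulminant = FALSE) {
  cfg <- list(
    acute_max_days = acute_max_days,
    subacute_max_days = subacute_max_days,
    lohf_max_days = lohf_max_days,
    pt_max_percent = pt_max_percent,
    inr_min = inr_min,
    labs_max_weeks = labs_max_weeks,
    death_threshold = death_threshold,
    atrophy_max_subscore = atrophy_max_subscore,
    indeterminate_fulminant = indeterminate_fulminant,
    unclassified_fulminant = unclassified_fulminant
  )
  validate_alf_config(cfg)
  structure(cfg, class = "alf_config")
}

validate_alf_config <- function(cfg) {
  stopifnot(
    cfg$acute_max_days >= 0,
    cfg$subacute_max_days > cfg$acute_max_days,
    cfg$lohf_max_days > cfg$subacute_max_days,
    cfg$pt_max_percent > 0,
    cfg$inr_min > 0,
    cfg$labs_max_weeks > 0,
    cfg$death_threshold >= 0, cfg$death_threshold <= 11,
    cfg$atrophy_max_subscore %in% c(1L, 2L),
    is.logical(cfg$indeterminate_fulminant),
    is.logical(cfg$unclassified_fulminant)
  )
  invisible(cfg)
}

#' Load configuration overrides from a YAML file
#'
#' Reads a YAML mapping whose keys are arguments of [alf_config()]; keys not
#' present keep their defaults. Unknown keys raise an error so typos do not
#' silently fall back to defaults.
#'
#' @param path path to a YAML file.
#' @return an `alf_config` object.
#' @export
read_alf_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(alf_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort_alf(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
              class = "alf_config_error")
  }
  do.call(alf_config, raw)
}
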