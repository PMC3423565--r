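#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used for every percentage printed in the 2010 nationwide-survey
#' report (e.g. 96/211 -> 45.5, 116/220 -> 52.7). Base [round()] rounds ties
#' to even and would disagree on exact .x5 values.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 1).
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(45.45, 1) # 45.5, not 45.4
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Hepatic coma grade levels
#'
#' Ordinal scale of hepatic encephalopathy severity: `none` (no psychiatric
#' disorder) then grades `I` through `V`.
#'
#' @return character vector of the six levels in increasing severity.
#' @export
coma_levels <- function() c("none", "I", "II", "III", "IV", "V")

#' Coerce to an ordered coma-grade factor
#'
#' @param x character vector with values among [coma_levels()] (NA allowed).
#' @return ordered factor on the coma scale.
#' @export
coma_grade <- function(x) {
  bad <- !is.na(x) & !x %in% coma_levels()
  if (any(bad)) {
    abort_alf(
      sprintf("unknown coma grade(s): %s", paste(unique(x[bad]), collapse = ", ")),
      class = "alf_validation_error"
    )
  }
  factor(as.character(x), levels = coma_levels(), ordered = TRUE)
}

# Integer rank of a coma grade: none=0 ... V=5. NA-preserving.
coma_rank <- function(x) {
  if (!is.ordered(x)) x <- coma_grade(x)
  as.integer(x) - 1L
}

# Condition helpers -----------------------------------------------------------

abort_alf <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "alf_error"), ...)
}

abort_missing <- function(message, ...) {
  abort_alf(message, class = "alf_missing_data_error", ...)
}

assert_data_frame <- function(x, arg = deparse(substitute(x))) {
  if (!is.data.frame(x)) {
    abort_alf(sprintf("`%s` must be a data frame", arg),
              class = "alf_validation_error")
  }
  invisible(x)
}

assert_columns <- function(x, cols, arg = deparse(substitute(x))) {
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols)) {
    abort_alf(
      sprintf("`%s` lacks required column(s): %s", arg,
              paste(missing_cols, collapse = ", ")),
      class = "alf_validation_error"
    )
  }
  invisible(x)
}
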