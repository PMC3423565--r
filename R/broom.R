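#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cohort summary
#'
#' Returns the per-stratum survival table: one row per (hepatitis,
#' category, treatment) stratum with survivor count, stratum size, and
#' one-decimal percentage.
#'
#' @param x an `alf_cohort_summary` from [summarize_cohort()].
#' @param ... unused.
#' @return a tibble.
#' @method tidy alf_cohort_summary
#' @export
tidy.alf_cohort_summary <- function(x, ...) {
  x$survival
}

#' Glance at a cohort summary
#'
#' One-row overview: cohort sizes and the headline survival aggregates
#' (medical-only overall and by hepatitis status, transplanted, overall).
#'
#' @param x an `alf_cohort_summary` from [summarize_cohort()].
#' @param ... unused.
#' @return a one-row tibble.
#' @method glance alf_cohort_summary
#' @export
glance.alf_cohort_summary <- function(x, ...) {
  if (x$n_total == 0) {
    return(tibble::tibble(n_total = 0L))
  }
  x$headline
}

#' Tidy confusion metrics
#'
#' Long form of an `alf_confusion` object: one row per metric.
#'
#' @param x an `alf_confusion` from [evaluate_predictions()].
#' @param ... unused.
#' @return tibble with columns `metric` and `value`.
#' @method tidy alf_confusion
#' @export
tidy.alf_confusion <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(unclass(x)),
                      cols = dplyr::everything(),
                      names_to = "metric", values_to = "value",
                      values_transform = as.numeric)
}

#' Glance at confusion metrics
#'
#' @param x an `alf_confusion` from [evaluate_predictions()].
#' @param ... unused.
#' @return the one-row metric tibble.
#' @method glance alf_confusion
#' @export
glance.alf_confusion <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
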