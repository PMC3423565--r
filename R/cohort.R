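#' The 2010 nationwide-survey stratum counts
#'
#' `survey_strata()` loads the packaged table of patient counts from the
#' 2010 nationwide survey of acute liver failure in Japan, one row per
#' (diagnosis category, hepatitis flag, treatment, outcome) stratum. The
#' 220 enrolled patients comprise 211 with ALF (96 without coma, 61
#' acute-type and 54 subacute-type with coma) and 9 with LOHF; 29 underwent
#' liver transplantation. Rows with `printed = FALSE` carry the per-stratum
#' split of the transplant outcomes, which the survey reports only in
#' aggregate (18 of 29 alive); their split is synthetic but sums to the
#' published marginals.
#'
#' `survey_records()` expands the strata into one row per patient
#' (`category`, `hepatitis`, `treatment`, `outcome`), the form the cohort
#' summaries consume.
#'
#' @return `survey_strata()`: tibble with columns `category` (`no_coma`,
#'   `acute`, `subacute`, `lohf`), `hepatitis` (logical), `treatment`,
#'   `outcome`, `count`, `printed`. `survey_records()`: tibble of 220 rows.
#' @export
#' @examples
#' sum(survey_strata()$count)  # 220
survey_strata <- function() {
  path <- system.file("extdata", "survey2010_strata.csv",
                      package = "alftriage", mustWork = TRUE)
  readr::read_csv(
    path,
    col_types = readr::cols(
      category = readr::col_character(),
      hepatitis = readr::col_logical(),
      treatment = readr::col_character(),
      outcome = readr::col_character(),
      count = readr::col_integer(),
      printed = readr::col_logical()
    )
  )
}

#' @rdname survey_strata
#' @export
survey_records <- function() {
  strata <- survey_strata()
  out <- tidyr::uncount(strata[strata$count > 0, ], weights = .data$count)
  out$printed <- NULL
  tibble::as_tibble(out)
}

survived_outcome <- function(outcome) {
  !is.na(outcome) & outcome %in% c("survived", "transplanted_alive")
}

#' Survival rate within a cohort stratum
#'
#' Counts survivors (`outcome` of `"survived"` or `"transplanted_alive"`)
#' among the records selected by the filter expressions, and reports the
#' percentage rounded half-up to one decimal — the convention of the
#' survey report. An empty stratum yields an `NA` percentage, never a
#' spurious zero.
#'
#' @param data data frame with an `outcome` column (plus whatever columns
#'   the filters reference).
#' @param ... optional dplyr-style filter expressions selecting the stratum,
#'   e.g. `treatment == "medical_only"`, `hepatitis`.
#' @return one-row tibble: `survived`, `total`, `percent`.
#' @export
#' @examples
#' survival_rate(survey_records(), treatment == "medical_only")  # 98/191, 51.3
survival_rate <- function(data, ...) {
  assert_data_frame(data)
  assert_columns(data, "outcome")
  sub <- dplyr::filter(data, ...)
  if (nrow(sub) > 0 && any(is.na(sub$outcome))) {
    abort_missing("outcome missing for some records in the stratum")
  }
  survived <- sum(survived_outcome(sub$outcome))
  total <- nrow(sub)
  tibble::tibble(
    survived = survived,
    total = total,
    percent = if (total == 0) NA_real_ else round_half_up(100 * survived / total)
  )
}

#' Stratified summary of an ALF cohort
#'
#' Reproduces the structure of the nationwide-survey report for any cohort:
#' diagnosis-category shares among ALF patients, the hepatitis /
#' non-hepatitis split with nested category shares, treatment shares among
#' all patients, survival per (hepatitis, category, treatment) stratum, and
#' the headline survival aggregates (medical-only, medical-only within and
#' without hepatitis, transplanted, overall). All percentages are rounded
#' half-up to one decimal. LOHF patients are kept as their own category and
#' folded into the with-hepatitis strata, as the survey does.
#'
#' @param data data frame with one row per patient and columns `category`
#'   (either survey short codes `no_coma`/`acute`/`subacute`/`lohf` or
#'   [classify_alf()] categories), a hepatitis flag (`hepatitis` or
#'   `fulminant_hepatitis`), `treatment`, and `outcome`; an optional
#'   `etiology` column adds an etiology breakdown.
#' @return an object of class `alf_cohort_summary`: a list of tibbles
#'   (`categories`, `hepatitis`, `treatment`, `survival`, `headline`, and
#'   optionally `etiology`) plus `n_total`. [generics::tidy()] returns the
#'   per-stratum survival table, [generics::glance()] the headline row.
#' @export
#' @examples
#' s <- summarize_cohort(survey_records())
#' glance(s)$overall_percent  # 52.7
summarize_cohort <- function(data) {
  assert_data_frame(data)
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) {
    return(structure(list(n_total = 0L, categories = tibble::tibble(),
                          hepatitis = tibble::tibble(),
                          treatment = tibble::tibble(),
                          survival = tibble::tibble(),
                          headline = tibble::tibble()),
                     class = "alf_cohort_summary"))
  }
  assert_columns(data, c("category", "treatment", "outcome"))
  hep_col <- if ("hepatitis" %in% names(data)) "hepatitis" else "fulminant_hepatitis"
  assert_columns(data, hep_col)
  data$hepatitis <- data[[hep_col]]
  data$category <- normalize_category(data$category)
  n_not_alf <- sum(data$category == "not_alf")
  data <- dplyr::filter(data, .data$category != "not_alf")
  if (nrow(data) == 0) {
    return(structure(list(n_total = 0L, n_excluded = n_not_alf,
                          categories = tibble::tibble(),
                          hepatitis_split = tibble::tibble(),
                          hepatitis_by_category = tibble::tibble(),
                          treatment = tibble::tibble(),
                          survival = tibble::tibble(),
                          headline = tibble::tibble()),
                     class = "alf_cohort_summary"))
  }

  pct <- function(num, den) round_half_up(100 * num / den)

  n_total <- nrow(data)
  alf <- dplyr::filter(data, .data$category != "lohf")
  n_alf <- nrow(alf)

  categories <- dplyr::count(data, .data$category, name = "count")
  categories$denominator <- ifelse(categories$category == "lohf",
                                   n_total, n_alf)
  categories$percent <- pct(categories$count, categories$denominator)

  hepatitis <- alf |>
    dplyr::group_by(.data$hepatitis) |>
    dplyr::summarise(count = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(percent = pct(.data$count, n_alf))
  nested <- alf |>
    dplyr::count(.data$hepatitis, .data$category, name = "count") |>
    dplyr::group_by(.data$hepatitis) |>
    dplyr::mutate(percent = pct(.data$count, sum(.data$count))) |>
    dplyr::ungroup()
  hepatitis <- list(split = hepatitis, by_category = nested)

  treatment <- dplyr::count(data, .data$treatment, name = "count") |>
    dplyr::mutate(percent = pct(.data$count, n_total))

  survival <- data |>
    dplyr::group_by(.data$hepatitis, .data$category, .data$treatment) |>
    dplyr::summarise(
      survived = sum(survived_outcome(.data$outcome)),
      total = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(percent = pct(.data$survived, .data$total))

  headline <- tibble::tibble(
    n_total = n_total,
    n_alf = n_alf,
    n_lohf = n_total - n_alf,
    medical = survival_rate(data, .data$treatment == "medical_only"),
    medical_hepatitis = survival_rate(
      data, .data$treatment == "medical_only", .data$hepatitis),
    medical_non_hepatitis = survival_rate(
      data, .data$treatment == "medical_only", !.data$hepatitis),
    transplant = survival_rate(data, .data$treatment == "transplant"),
    overall = survival_rate(data)
  ) |> tidyr::unpack(
    cols = c("medical", "medical_hepatitis", "medical_non_hepatitis",
             "transplant", "overall"),
    names_sep = "_"
  )

  out <- list(
    n_total = n_total,
    n_excluded = n_not_alf,
    categories = categories,
    hepatitis_split = hepatitis$split,
    hepatitis_by_category = hepatitis$by_category,
    treatment = treatment,
    survival = survival,
    headline = headline
  )
  if ("etiology" %in% names(data)) {
    out$etiology <- data |>
      dplyr::count(.data$category, .data$etiology, name = "count") |>
      dplyr::group_by(.data$category) |>
      dplyr::mutate(percent = pct(.data$count, sum(.data$count))) |>
      dplyr::ungroup()
  }
  structure(out, class = "alf_cohort_summary")
}

# Map classify_alf() categories onto the survey's short codes.
normalize_category <- function(category) {
  category <- as.character(category)
  map <- c(ALF_WITHOUT_COMA = "no_coma", ALF_WITH_COMA_ACUTE = "acute",
           ALF_WITH_COMA_SUBACUTE = "subacute", LOHF = "lohf",
           NOT_ALF = "not_alf", no_coma = "no_coma", acute = "acute",
           subacute = "subacute", lohf = "lohf", not_alf = "not_alf")
  unknown <- setdiff(unique(category), c(names(map), NA))
  if (length(unknown)) {
    abort_alf(sprintf("cannot summarize category value(s): %s",
                      paste(unknown, collapse = ", ")),
              class = "alf_validation_error")
  }
  unname(map[category])
}

#' @export
print.alf_cohort_summary <- function(x, ...) {
  cat(sprintf("ALF cohort summary: %d patients (%d ALF, %d LOHF)\n",
              x$n_total, x$headline$n_alf %||% NA, x$headline$n_lohf %||% NA))
  if (x$n_total > 0) {
    cat(sprintf("  overall survival %s%% (%d/%d); medical-only %s%% (%d/%d); transplanted %s%% (%d/%d)\n",
                x$headline$overall_percent, x$headline$overall_survived,
                x$headline$overall_total,
                x$headline$medical_percent, x$headline$medical_survived,
                x$headline$medical_total,
                x$headline$transplant_percent, x$headline$transplant_survived,
                x$headline$transplant_total))
    cat("Per-stratum survival:\n")
    print(x$survival, ...)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Confusion-matrix evaluation of death-call predictions
#'
#' Compares predicted deaths (e.g. `predicted_death` from
#' [score_prognosis()], or `candidate` from
#' [assess_transplant_criteria()]) against observed deaths, and computes
#' the standard metrics: sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, positive and negative predictive values, and accuracy
#' `(tp+tn)/n`. "Positive" means death. Ratios with a zero denominator are
#' reported as `NA`, never 0.
#'
#' @param predicted_death,observed_death equal-length, non-empty logical
#'   vectors without NA.
#' @return an object of class `alf_confusion` (a one-row tibble with `tp`,
#'   `fp`, `tn`, `fn`, `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy`).
#' @export
#' @examples
#' evaluate_predictions(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
evaluate_predictions <- function(predicted_death, observed_death) {
  if (length(predicted_death) != length(observed_death)) {
    abort_alf("predicted and observed vectors must have equal length",
              class = "alf_alignment_error")
  }
  if (length(predicted_death) == 0) {
    abort_alf("cannot evaluate an empty prediction set",
              class = "alf_alignment_error")
  }
  if (any(is.na(predicted_death)) || any(is.na(observed_death))) {
    abort_missing("predictions and observations must not contain NA")
  }
  tp <- sum(predicted_death & observed_death)
  fp <- sum(predicted_death & !observed_death)
  tn <- sum(!predicted_death & !observed_death)
  fn <- sum(!predicted_death & observed_death)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    accuracy = (tp + tn) / (tp + fp + tn + fn)
  )
  class(out) <- c("alf_confusion", class(out))
  out
}
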