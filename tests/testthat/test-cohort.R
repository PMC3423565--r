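test_that("percentages round half-up to one decimal as the survey prints them", {
  expect_equal(round_half_up(100 * 96 / 211), 45.5)
  expect_equal(round_half_up(100 * 116 / 220), 52.7)
  expect_equal(round_half_up(45.45), 45.5)   # ties go up, not to even
  expect_equal(round_half_up(45.44), 45.4)
  expect_equal(round_half_up(-1.25, 1), -1.3)
})

test_that("the survey cohort summary reproduces every printed aggregate", {
  s <- summarize_cohort(survey_records())
  expect_equal(s$n_total, 220)

  cats <- tibble::deframe(s$categories[, c("category", "count")])
  expect_equal(cats[["no_coma"]], 96)
  expect_equal(cats[["acute"]], 61)
  expect_equal(cats[["subacute"]], 54)
  expect_equal(cats[["lohf"]], 9)
  pcts <- tibble::deframe(s$categories[, c("category", "percent")])
  expect_equal(pcts[["no_coma"]], 45.5)
  expect_equal(pcts[["acute"]], 28.9)
  expect_equal(pcts[["subacute"]], 25.6)

  hep <- s$hepatitis_split
  expect_equal(hep$count[hep$hepatitis], 188)
  expect_equal(hep$percent[hep$hepatitis], 89.1)
  expect_equal(hep$count[!hep$hepatitis], 23)
  expect_equal(hep$percent[!hep$hepatitis], 10.9)

  nested <- s$hepatitis_by_category
  pick <- function(h, cat) nested[nested$hepatitis == h & nested$category == cat, ]
  expect_equal(pick(TRUE, "no_coma")$count, 85)
  expect_equal(pick(TRUE, "no_coma")$percent, 45.2)
  expect_equal(pick(TRUE, "acute")$count, 54)
  expect_equal(pick(TRUE, "acute")$percent, 28.7)
  expect_equal(pick(TRUE, "subacute")$count, 49)
  expect_equal(pick(TRUE, "subacute")$percent, 26.1)
  expect_equal(pick(FALSE, "no_coma")$count, 11)
  expect_equal(pick(FALSE, "no_coma")$percent, 47.8)
  expect_equal(pick(FALSE, "acute")$count, 7)
  expect_equal(pick(FALSE, "acute")$percent, 30.4)
  expect_equal(pick(FALSE, "subacute")$count, 5)
  expect_equal(pick(FALSE, "subacute")$percent, 21.7)

  tr <- s$treatment
  expect_equal(tr$count[tr$treatment == "transplant"], 29)
  expect_equal(tr$percent[tr$treatment == "transplant"], 13.2)
  expect_equal(tr$count[tr$treatment == "medical_only"], 191)
  expect_equal(tr$percent[tr$treatment == "medical_only"], 86.8)
})

test_that("survival rates reproduce the printed numerators and denominators", {
  records <- survey_records()
  expect_equal(survival_rate(records, treatment == "medical_only"),
               tibble::tibble(survived = 98, total = 191, percent = 51.3))
  expect_equal(survival_rate(records, treatment == "medical_only", hepatitis),
               tibble::tibble(survived = 92, total = 168, percent = 54.8))
  expect_equal(survival_rate(records, treatment == "medical_only", !hepatitis),
               tibble::tibble(survived = 6, total = 23, percent = 26.1))
  expect_equal(survival_rate(records, treatment == "transplant"),
               tibble::tibble(survived = 18, total = 29, percent = 62.1))
  expect_equal(survival_rate(records),
               tibble::tibble(survived = 116, total = 220, percent = 52.7))

  med_hep <- function(cat) {
    survival_rate(records, treatment == "medical_only", hepatitis,
                  category == cat)
  }
  expect_equal(med_hep("no_coma"),
               tibble::tibble(survived = 72, total = 83, percent = 86.7))
  expect_equal(med_hep("acute"),
               tibble::tibble(survived = 13, total = 41, percent = 31.7))
  expect_equal(med_hep("subacute"),
               tibble::tibble(survived = 7, total = 36, percent = 19.4))
  expect_equal(med_hep("lohf"),
               tibble::tibble(survived = 0, total = 8, percent = 0))

  med_non <- function(cat) {
    survival_rate(records, treatment == "medical_only", !hepatitis,
                  category == cat)
  }
  expect_equal(med_non("no_coma"),
               tibble::tibble(survived = 5, total = 11, percent = 45.5))
  expect_equal(med_non("acute"),
               tibble::tibble(survived = 1, total = 7, percent = 14.3))
  expect_equal(med_non("subacute"),
               tibble::tibble(survived = 0, total = 5, percent = 0))
})

test_that("the coma-positive hepatitis group matches the printed 112-patient breakdown", {
  records <- survey_records()
  fh <- dplyr::filter(records, hepatitis, category != "no_coma")
  expect_equal(nrow(fh), 112)
  expect_equal(sum(fh$treatment == "medical_only" & fh$outcome == "survived"), 20)
  expect_equal(sum(fh$treatment == "medical_only" & fh$outcome == "died"), 65)
  expect_equal(sum(fh$treatment == "transplant"), 27)
  expect_equal(round_half_up(100 * 20 / 112), 17.9)
  expect_equal(round_half_up(100 * 65 / 112), 58.0)
  expect_equal(round_half_up(100 * 27 / 112), 24.1)
})

test_that("degenerate cohorts are handled without division by zero", {
  one <- tibble::tibble(category = "acute", hepatitis = TRUE,
                        treatment = "medical_only", outcome = "survived")
  s <- summarize_cohort(one)
  expect_equal(s$categories$percent, 100)
  expect_equal(survival_rate(one)$percent, 100)

  empty <- summarize_cohort(one[0, ])
  expect_equal(empty$n_total, 0L)
  expect_s3_class(glance(empty), "tbl_df")

  # empty stratum yields an undefined rate, not zero
  expect_true(is.na(survival_rate(one, treatment == "transplant")$percent))
})

test_that("every partition emitted sums to the cohort size", {
  cohort <- simulate_cohort(500, seed = 7)
  cl <- classify_alf(cohort)
  cl$outcome <- cohort$outcome
  s <- summarize_cohort(cl)
  expect_equal(sum(s$categories$count), s$n_total)
  expect_equal(sum(s$treatment$count), s$n_total)
  expect_equal(sum(s$survival$total), s$n_total)
  expect_equal(sum(s$hepatitis_split$count) + sum(s$categories$count[s$categories$category == "lohf"]),
               s$n_total)
})

test_that("confusion metrics match a brute-force 2x2 count", {
  perfect <- evaluate_predictions(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)

  all_pos <- evaluate_predictions(rep(TRUE, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
  expect_true(is.na(all_pos$npv))   # zero denominator reported as missing

  set.seed(606)
  pred <- stats::runif(200) < 0.5
  obs <- stats::runif(200) < 0.6
  m <- evaluate_predictions(pred, obs)
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (i in 1:200) {
    if (pred[i] && obs[i]) tp <- tp + 1
    else if (pred[i] && !obs[i]) fp <- fp + 1
    else if (!pred[i] && !obs[i]) tn <- tn + 1
    else fn <- fn + 1
  }
  expect_equal(m$tp, tp)
  expect_equal(m$fp, fp)
  expect_equal(m$tn, tn)
  expect_equal(m$fn, fn)
  expect_equal(m$sensitivity, tp / (tp + fn))
  expect_equal(m$specificity, tn / (tn + fp))
  expect_equal(m$ppv, tp / (tp + fp))
  expect_equal(m$npv, tn / (tn + fn))
  expect_equal(m$accuracy, (tp + tn) / 200)

  expect_error(evaluate_predictions(TRUE, c(TRUE, FALSE)),
               class = "alf_alignment_error")
  expect_error(evaluate_predictions(logical(0), logical(0)),
               class = "alf_alignment_error")
})

test_that("tidy and glance methods expose the summary tables", {
  s <- summarize_cohort(survey_records())
  expect_equal(glance(s)$overall_percent, 52.7)
  expect_equal(glance(s)$medical_percent, 51.3)
  td <- tidy(s)
  expect_true(all(c("hepatitis", "category", "treatment", "survived",
                    "total", "percent") %in% names(td)))
  m <- evaluate_predictions(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(nrow(tidy(m)), 9)
  expect_s3_class(glance(m), "tbl_df")
})
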