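# Independent subscore oracle, hand-coded straight from the printed grid.
oracle_subscore <- function(parameter, value) {
  if (parameter == "oc_days") {
    if (value <= 5) return(0L)
    if (value >= 6 && value <= 10) return(1L)
    return(2L)
  }
  if (parameter == "pt") {
    if (value > 20) return(0L)
    if (value > 5 && value <= 20) return(1L)
    return(2L)
  }
  if (parameter == "tb") {
    if (value < 10) return(0L)
    if (value >= 10 && value < 15) return(1L)
    return(2L)
  }
  if (parameter == "dt_ratio") {
    if (value >= 0.7) return(0L)
    if (value >= 0.5 && value < 0.7) return(1L)
    return(2L)
  }
  if (parameter == "plt") {
    if (value > 10) return(0L)
    if (value > 5 && value <= 10) return(1L)
    return(2L)
  }
  if (parameter == "atrophy") return(if (isTRUE(value)) 1L else 0L)
  stop("unknown parameter")
}

# Each continuous parameter probed at both cut points +/- a small epsilon,
# plus interior values; oc_days at the integer boundaries.
grid_values <- list(
  oc_days = c(0, 5, 6, 10, 11, 40),
  pt = c(2, 5, 5.001, 20, 20.001, 90),
  tb = c(3, 9.999, 10, 14.999, 15, 30),
  dt_ratio = c(0.2, 0.499, 0.5, 0.699, 0.7, 0.95),
  plt = c(2, 5, 5.001, 10, 10.001, 30),
  atrophy = c(FALSE, TRUE)
)

test_that("subscores match the hand-coded lookup on the boundary grid", {
  for (p in names(grid_values)) {
    for (v in grid_values[[p]]) {
      expect_equal(score_component(p, v), oracle_subscore(p, v),
                   label = sprintf("%s(%s)", p, v))
    }
  }
  # spec'd worked boundary cases
  expect_equal(score_component("pt", 20), 1L)
  expect_equal(score_component("tb", 15), 2L)
  expect_equal(score_component("dt_ratio", 0.7), 0L)
})

test_that("totals over the exhaustive boundary grid equal the oracle and stay in 0..11", {
  combos <- expand.grid(oc = grid_values$oc_days, pt = grid_values$pt,
                        tb = grid_values$tb, dt = grid_values$dt_ratio,
                        plt = grid_values$plt, atr = grid_values$atrophy)
  records <- tibble::tibble(
    patient_id = sprintf("g%05d", seq_len(nrow(combos))),
    pt_percent = combos$pt,
    total_bilirubin = combos$tb,
    direct_bilirubin = NA_real_,
    dt_ratio = combos$dt,
    platelets = combos$plt,
    liver_atrophy = as.logical(combos$atr),
    coma_grade = "II",
    onset_to_encephalopathy_days = as.integer(combos$oc)
  )
  scored <- score_prognosis(records)
  expected_total <- mapply(function(oc, pt, tb, dt, plt, atr) {
    oracle_subscore("oc_days", oc) + oracle_subscore("pt", pt) +
      oracle_subscore("tb", tb) + oracle_subscore("dt_ratio", dt) +
      oracle_subscore("plt", plt) + oracle_subscore("atrophy", atr)
  }, combos$oc, combos$pt, combos$tb, combos$dt, combos$plt, combos$atr)
  expect_equal(scored$total, as.integer(expected_total))
  expect_true(all(scored$total >= 0 & scored$total <= 11))
  expect_equal(scored$predicted_death, scored$total >= 5)
})

test_that("the all-maximum and all-minimum presentations bracket the scale", {
  worst <- score_prognosis(make_record(
    onset_to_encephalopathy_days = 12L, pt_percent = 4, total_bilirubin = 16,
    direct_bilirubin = 6.4, platelets = 4, liver_atrophy = TRUE))
  expect_equal(worst$total, 11L)
  expect_true(worst$predicted_death)
  expect_equal(worst$band, ">90%")

  best <- score_prognosis(make_record(
    onset_to_encephalopathy_days = 3L, pt_percent = 35, total_bilirubin = 5,
    direct_bilirubin = 4, platelets = 15, liver_atrophy = FALSE))
  expect_equal(best$total, 0L)
  expect_false(best$predicted_death)
})

test_that("mortality bands reproduce the published table", {
  b <- mortality_band(0:11)
  expect_equal(b$label,
               c(rep("<30%", 4), "50-60%", "70-80%", "80-90%", rep(">90%", 5)))
  expect_equal(mortality_band(7)$lower_percent, 90)
  expect_equal(mortality_band(4)$lower_percent, 50)
  expect_equal(mortality_band(4)$upper_percent, 60)
  expect_equal(mortality_band(0)$upper_percent, 30)
  expect_equal(mortality_band(11)$label, ">90%")
  # bands partition 0..11 with non-decreasing lower bounds
  expect_true(all(diff(b$lower_percent) >= 0))
  expect_true(all(b$lower_percent <= b$upper_percent))
  expect_error(mortality_band(12), class = "alf_domain_error")
  expect_error(mortality_band(-1), class = "alf_domain_error")
})

test_that("worsening any single parameter never decreases the total", {
  set.seed(303)
  worsen <- list(
    oc_days = function(v) v + sample(1:20, 1),
    pt = function(v) max(v - stats::runif(1, 0, v * 0.9), 0.1),
    tb = function(v) v + stats::runif(1, 0, 20),
    dt_ratio = function(v) max(v - stats::runif(1, 0, v * 0.9), 0.01),
    plt = function(v) max(v - stats::runif(1, 0, v * 0.9), 0.1),
    atrophy = function(v) TRUE
  )
  for (i in 1:100) {
    base <- list(oc_days = sample(0:30, 1), pt = stats::runif(1, 1, 60),
                 tb = stats::runif(1, 1, 30), dt_ratio = stats::runif(1, 0.1, 0.95),
                 plt = stats::runif(1, 1, 30), atrophy = FALSE)
    total0 <- sum(purrr::imap_int(base, ~ score_component(.y, .x)))
    p <- sample(names(base), 1)
    base[[p]] <- worsen[[p]](base[[p]])
    total1 <- sum(purrr::imap_int(base, ~ score_component(.y, .x)))
    expect_gte(total1, total0)
  }
})

test_that("scoring refuses records below grade II or with missing parameters", {
  expect_error(score_prognosis(make_no_coma_record()),
               class = "alf_precondition_error")
  err <- tryCatch(
    score_prognosis(make_record(platelets = NA_real_)),
    error = identity
  )
  expect_s3_class(err, "alf_missing_data_error")
  expect_match(conditionMessage(err), "plt")

  partial <- score_prognosis(make_record(platelets = NA_real_),
                             allow_partial = TRUE)
  expect_true(partial$partial)
  expect_true(is.na(partial$total))
  expect_equal(partial$total_max - partial$total_min, 2L)
})

test_that("atrophy subscore policy 0/2 raises the maximum total to 12", {
  cfg <- alf_config(atrophy_max_subscore = 2)
  expect_equal(score_component("atrophy", TRUE, cfg), 2L)
  expect_equal(score_component("atrophy", FALSE, cfg), 0L)
})

test_that("transplant candidacy counts the five criteria with printed strictness", {
  a <- assess_transplant_criteria(make_record(
    age_years = 50L, onset_to_encephalopathy_days = 12L, pt_percent = 30,
    total_bilirubin = 10, direct_bilirubin = 8))
  expect_equal(a$n_met, 2L)
  expect_true(a$candidate)

  a <- assess_transplant_criteria(make_record(
    age_years = 30L, onset_to_encephalopathy_days = 5L, pt_percent = 15,
    total_bilirubin = 10, direct_bilirubin = 8))
  expect_equal(a$n_met, 0L)
  expect_false(a$candidate)

  # every boundary at its printed strictness: age/interval/TB inclusive,
  # PT and D/T strict
  a <- assess_transplant_criteria(make_record(
    age_years = 45L, onset_to_encephalopathy_days = 11L, pt_percent = 10,
    total_bilirubin = 18.0, direct_bilirubin = 18.0 * 0.67))
  expect_true(a$crit_age)
  expect_true(a$crit_interval)
  expect_false(a$crit_pt)
  expect_true(a$crit_bilirubin)
  expect_false(a$crit_dt_ratio)
  expect_equal(a$n_met, 3L)

  expect_error(assess_transplant_criteria(make_no_coma_record()),
               class = "alf_precondition_error")
})

test_that("candidacy equals a brute-force criterion count on random records", {
  set.seed(404)
  n <- 10000
  records <- tibble::tibble(
    patient_id = sprintf("r%05d", 1:n),
    age_years = sample(18:90, n, replace = TRUE),
    onset_to_encephalopathy_days = sample(0:60, n, replace = TRUE),
    pt_percent = stats::runif(n, 1, 45),
    total_bilirubin = stats::runif(n, 1, 30),
    direct_bilirubin = NA_real_,
    dt_ratio = stats::runif(n, 0.1, 0.99),
    coma_grade = sample(c("II", "III", "IV", "V"), n, replace = TRUE)
  )
  a <- assess_transplant_criteria(records)
  brute <- (records$age_years >= 45) + (records$onset_to_encephalopathy_days >= 11) +
    (records$pt_percent < 10) + (records$total_bilirubin >= 18.0) +
    (records$dt_ratio < 0.67)
  expect_equal(a$n_met, as.integer(brute))
  expect_equal(a$candidate, brute >= 2)
})

test_that("day-5 reassessment requires both improvements and only rescues", {
  cand <- assess_transplant_criteria(make_record(
    age_years = 50L, coma_grade = "IV", onset_to_encephalopathy_days = 12L,
    pt_percent = 8, total_bilirubin = 19, direct_bilirubin = 9))
  expect_true(cand$candidate)

  r <- reassess_day5(cand, coma_day5 = "II", pt_day5 = 60)
  expect_true(r$reassessed_alive)   # 2-grade attenuation and PT > 50
  expect_false(r$candidate_final)

  cand3 <- cand
  cand3$coma_grade <- coma_grade("III")
  r <- reassess_day5(cand3, coma_day5 = "II", pt_day5 = 60)
  expect_false(r$reassessed_alive)  # only one grade, not down to I

  r <- reassess_day5(cand, coma_day5 = "I", pt_day5 = 50)
  expect_false(r$reassessed_alive)  # PT must exceed 50

  r <- reassess_day5(cand, coma_day5 = "I", pt_day5 = 50.5)
  expect_true(r$reassessed_alive)   # improvement to grade I suffices

  non_cand <- assess_transplant_criteria(make_record(
    age_years = 30L, onset_to_encephalopathy_days = 5L, pt_percent = 15,
    total_bilirubin = 10, direct_bilirubin = 8))
  expect_error(reassess_day5(non_cand, "I", 80),
               class = "alf_precondition_error")
})

test_that("reassessment can flip death to alive but never the reverse", {
  set.seed(505)
  for (i in 1:200) {
    cand <- assess_transplant_criteria(make_record(
      age_years = 50L,
      coma_grade = sample(c("II", "III", "IV", "V"), 1),
      onset_to_encephalopathy_days = 12L, pt_percent = 8,
      total_bilirubin = 19, direct_bilirubin = 9))
    r <- reassess_day5(cand,
                       coma_day5 = sample(coma_levels(), 1),
                       pt_day5 = stats::runif(1, 5, 90))
    # candidacy (the "death" call) can only be withdrawn, never created
    expect_true(r$candidate_final <= r$candidate)
    expect_equal(r$reassessed_alive, r$coma_improved && r$pt_improved)
  }
})
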