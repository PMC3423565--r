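# Build a valid single patient record, overridable field by field.
make_record <- function(...) {
  base <- tibble::tibble(
    patient_id = "p1",
    age_years = 40L,
    is_pediatric = FALSE,
    onset_to_encephalopathy_days = 8L,
    onset_to_labs_weeks = 1,
    pt_percent = 30,
    inr = NA_real_,
    total_bilirubin = 12,
    direct_bilirubin = 6,
    platelets = 8,
    liver_atrophy = FALSE,
    coma_grade = "II",
    etiology = "I_viral",
    etiology_sub = "HBV_transient",
    prior_liver_function_normal = TRUE,
    habitual_alcohol_as_cause = FALSE,
    treatment = "medical_only",
    outcome = "survived"
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

# Integer severity rank of a coma grade (none=0 ... V=5).
rank_of <- function(g) match(as.character(g), coma_levels()) - 1L

# A record with no encephalopathy (interval must then be absent).
make_no_coma_record <- function(...) {
  make_record(coma_grade = "none",
              onset_to_encephalopathy_days = NA_integer_, ...)
}
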