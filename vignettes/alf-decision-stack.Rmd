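---
title: "Methods: the Japanese acute-liver-failure decision stack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Japanese acute-liver-failure decision stack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alftriage)
```

This vignette documents the models and conventions behind `alftriage` in
enough detail that a maintainer can judge every rule, boundary, and design
choice without reading the sources.

## The clinical problem

Acute liver failure (ALF) is severe acute impairment of liver function —
coagulopathy and, in the worst cases, hepatic encephalopathy — arising in a
previously normal liver. In Japan the syndrome is dominated by viral
hepatitis, the first-line therapy is artificial liver support rather than
immediate transplantation, and the national diagnostic criteria differ from
the European/US ones. The package implements the Japanese stack as data
transformations over patient-record tables: coma grading, the 2011
diagnostic classification, the etiology taxonomy with its
fulminant-hepatitis flag, the 1996 transplant guideline, the 2011 prognostic
score, survey-style cohort summaries, and a synthetic cohort generator.

## Record model and unit conventions

One row per patient. PT is stored as a percent of the standardized value
(the Japanese laboratory convention; lower is worse) and INR as a separate
field; the package never converts between them because no conversion
formula is defined for the heterogeneous commercial assays involved.
Bilirubins are mg/dL, platelets 10⁴/µL. The direct/total bilirubin ratio is
derived whenever both bilirubins are present (undefined at total = 0, left
missing rather than invented); a supplied ratio is honoured only when it
cannot be derived. Ages are whole years; a pediatric grading table is
selected by an explicit `is_pediatric` flag rather than an age cutoff, since
no numeric boundary between the adult and pediatric grading tables is
defined.

Intervals are whole days counted inclusively from the calendar day of first
disease symptoms, so "within 10 days" means interval ≤ 10. The
onset-to-encephalopathy interval must be present exactly when the coma
grade is II or worse — it is undefined for patients who never reached
grade II, and the validator enforces both directions.

Missing values are empty cells (CSV) or `null` (JSON). No operation imputes:
each either tolerates a documented missing field or refuses with an error
naming the field and patient.

## Coma grading

Grading maps structured feature flags to the ordinal scale none < I < II <
III < IV < V and always returns the *highest* grade whose defining criterion
holds, so mixed presentations resolve upward. Only the defining
psychiatric-disorder manifestations decide membership; the illustrative
reference items that accompany the adult table overlap across grades and are
deliberately not inputs. Grade III accepts any of its three listed
manifestations (excitation/delirium; sleeping mostly but opening eyes to
stimulation; following only simple orders) — the table lists them as
alternatives. Grades IV and V both require complete loss of consciousness
and are separated by the response to painful stimuli; the two pain-response
flags are mutually exclusive and contradictory input is an error, not a
tie-break. In the pediatric table the grade-I/grade-II distinction for
infants ("does not laugh aloud" vs. "does not laugh even when played with")
is taken literally as printed.

## Diagnostic classification

The laboratory criterion is PT ≤ 40 % **or** INR ≥ 1.5. The 2011 wording
("40 % or less") makes the PT boundary inclusive; the earlier 2002 criteria
said "less than 40 %", and the 2011 wording governs here since the 2011
criteria are what is implemented. Exclusions (checked in order after the
lab criterion): habitual alcohol as the cause (alcoholic hepatitis is
acute-on-chronic disease), then any prior impairment of liver function. Both
are supplied as input flags — chart-history adjudication (HBV carrier
status, autoimmune flares, fatty liver with a non-alcohol acute insult) is
the data provider's job, not the classifier's.

With no or grade-I encephalopathy, qualifying labs within 8 weeks give ALF
without coma; later labs exceed the diagnostic window. With grade ≥ II
encephalopathy the interval decides: ≤ 10 days acute, 11–56 subacute,
57–168 LOHF, and beyond 168 days outside every window. The LOHF window
"8–24 weeks" is implemented in days (57–168) so it is exactly continuous
with the subacute upper bound of 56 days; where week counting and day
counting disagree at the 8-week boundary, the day count wins, as a stated
convention. The category function of the interval is therefore a step
function with no gaps or overlaps, which the tests sweep exhaustively.

The fulminant-hepatitis flag marks histological-hepatitis etiologies (viral
I, autoimmune II, drug allergy III-1) among non-excluded patients.
Indeterminate etiology (IX) counts as hepatitis-compatible by default
because the nationwide survey tallies indeterminate cases inside its
hepatitis group; unclassified (X, insufficient examinations) defaults to
incompatible. Both policies are configuration switches because the taxonomy
itself does not settle them.

## The 1996 transplant guideline

Step 1 counts five poor-prognosis criteria at coma onset (age ≥ 45 y,
interval ≥ 11 d, PT < 10 %, TB ≥ 18.0 mg/dL, D/T < 0.67); 2 or more make
the patient a candidate. The printed inequality directions are kept exactly —
age, interval and bilirubin inclusive, PT and D/T strict — even though they
differ in strictness from the 2011 score's cut points; no harmonisation is
attempted, since the two instruments were published independently. Step 2,
five days later, revises the prognosis to "alive" only when the coma has
improved to grade ≤ I *or* attenuated by ≥ 2 grades (a logical OR, counting
none–I–II–III–IV–V as unit steps) *and* PT exceeds 50 %. Reassessment is
one-directional: it can only withdraw a candidacy, never create one, and
calling it on a non-candidate is a precondition error.

## The 2011 prognostic score

Six parameters are binned 0/1/2 at the published cut points (see the README
table); the bins partition each parameter's domain with no gaps, and the
boundary side of every cut is taken from the printed interval notation. The
liver-atrophy row prints only two cells (absent/present), so its subscore
is 0/1 and the maximum total is 11; because the table layout leaves the
column assignment of "present" typographically ambiguous, the
`atrophy_max_subscore` option allows 0/2. The death call is total ≥ 5,
inclusive, exposed as `death_threshold`. Mortality bands (> 90 % at ≥ 7,
80–90, 70–80, 50–60 at 6/5/4, < 30 % at ≤ 3) partition 0–11 with
non-decreasing lower bounds.

The score is defined for patients with fulminant hepatitis or LOHF, i.e.
grade ≥ II encephalopathy — the onset-to-encephalopathy parameter does not
exist otherwise — so scoring refuses records below grade II. Missing
parameters are refused rather than defaulted; `allow_partial = TRUE`
instead reports the attainable total range (`total_min`/`total_max`) for
incomplete records, an explicit extension beyond the published system and
flagged per row as such.

No survival regression or recalibration is attempted beyond the printed
bands, and the related instruments that require unpublished model
structures or external thresholds (King's College criteria, MELD,
cluster/decision-tree predictors) are out of scope.

## Cohort analytics and the survey fixture

`inst/extdata/survey2010_strata.csv` transcribes the 2010 nationwide survey
as counts per (category × hepatitis × treatment × outcome) stratum:
220 patients, 211 ALF (96/61/54 across no-coma/acute/subacute) plus 9 LOHF,
29 transplanted. The survey prints transplant survival only in aggregate
(18/29), so the per-stratum transplant outcome split in the fixture is a
synthetic allocation flagged `printed = FALSE`; it sums to the published
marginals, and golden tests assert printed aggregates only. One printed
denominator is internally inconsistent — "2 of 7 patients (22.2 %)" for
indeterminate-etiology LOHF, where the LOHF cohort is 9 and 2/9 = 22.2 % —
and the package uses 9, treating the printed 7 as a typographical error.

Percentages are rounded half-up to one decimal, which reproduces every
printed value (banker's rounding would not). Denominators follow the
survey's conventions exactly: category shares out of the 211 ALF patients,
treatment shares out of all 220, medical-only survival out of 191 with
transplanted patients excluded, overall survival out of 220 with them
included. Empty strata yield missing rates, never zero. Confusion metrics
("positive" = death) report zero-denominator ratios as missing.

## The synthetic cohort generator

The generator emulates the survey's *structure*: stratum probabilities,
per-stratum transplant probabilities, and per-(stratum, treatment) survival
probabilities are all derived from the fixture counts, so the generator's
targets and the golden tests share one source of truth. Etiology mixes per
stratum follow the survey's printed marginals (viral 43/29/19/3 and
indeterminate 27/17/22/2 across no-coma/acute/subacute/LOHF; the
non-hepatitis causes 6 circulatory, 5 malignant infiltration,
4 post-operative, 3 metabolic, 3 miscellaneous, 2 drug toxicity), with the
unpublished remainder inside the hepatitis strata split evenly between
autoimmune hepatitis and drug allergy.

Laboratory values have **no** published distributions, so they are
synthetic package constants: truncated log-normal distributions per
category (inverse-CDF sampling), truncated so that every draw is consistent
with the record's assigned class — PT in (1, 40] so the lab criterion always
holds, onset intervals drawn uniformly inside the assigned window (0–10,
11–56, 57–168 days), coma grades II–V for coma strata and none/I otherwise,
D/T ratios uniform on category-specific ranges, and atrophy prevalence
rising with severity (0.05/0.2/0.5/0.6). Location parameters are ordered by
severity (lower PT, higher bilirubin with coma and later onset) to look
clinically plausible. Ages are truncated-normal around 48 ± 17 years, all
adult. A single integer seed drives one private RNG stream and the caller's
`.Random.seed` is restored afterwards.

Consequently the generator is a *structural* emulation: classification,
scoring and summarisation can be property-tested against known strata, and
frequencies converge to the fixture targets by the law of large numbers
(tests check a 10,000-patient cohort within 3 binomial standard errors).
What passing these tests does **not** show: that real lab values follow
log-normals, that real etiology and severity are independent given the
stratum, or that the prognostic score attains its published external
accuracy — the external validation cohorts are unpublished, and only the
metric *formulas* are verified here (by brute-force 2×2 counts). The
generator draws one lab panel per patient; day-5 trajectories are supplied
by the caller where needed.

## Numerical and degenerate-input choices

* Boundary values are compared with the exact printed inequalities; the
  test grids probe every cut point and cut point ± 10⁻³. Where a test needs
  an exact ratio at a boundary (e.g. D/T = 0.7) the ratio is supplied
  directly rather than via a bilirubin division, avoiding floating-point
  drift across a cut point.
* Ties across grading criteria resolve to the higher grade; there are no
  other ties anywhere (the bins partition their domains).
* Empty cohorts summarise to empty tables; empty strata give missing rates;
  zero-denominator metrics are missing, never zero.
* Problem sizes in the test-suite: exhaustive grids of 2 048–4 608
  score combinations, 10 000-record property tests for the guideline and
  the generator, and 201-point interval sweeps — sizes chosen to keep the
  whole suite comfortably under a minute while leaving binomial noise well
  below the 3-SE test bands.

## Known limitations

* The classifier adjudicates nothing from raw history: prior liver
  function, alcohol causation, and the pediatric flag are inputs.
* No calendar-date arithmetic; callers supply intervals.
* The 2002 fulminant-hepatitis criteria exist only as the etiology-based
  hepatitis flag, not as a separate classifier; severity instruments from
  other jurisdictions are out of scope.
* Fixture-derived generator defaults inherit the survey's small strata
  (e.g. 9 LOHF patients): the zero observed survival in some strata becomes
  a hard zero probability, which is faithful to the data but fragile as an
  estimate of the true rate.
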