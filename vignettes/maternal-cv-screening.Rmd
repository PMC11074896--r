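---
title: "Encounter-level maternal cardiovascular risk screening: model, generator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encounter-level maternal cardiovascular risk screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcvrisk)
```

## The problem

Cardiovascular conditions — hypertensive disorders of pregnancy foremost —
are a leading cause of maternal mortality in the United States, and they
are frequently recognized late. `mcvrisk` implements an encounter-level
screening procedure over longitudinal obstetric EHR data: every clinical
visit is evaluated independently against a clinician-defined set of risk
factors, encounters with any sign of risk produce a *risk profile*
(standard or red-flag), and profiles are then paired with the first
recorded diagnosis or intervention of nine tracked cardiovascular
conditions within the same pregnancy. The quantity of interest is the
*delta*: the signed number of days between the anchoring risk profile and
that first recorded diagnosis or intervention. A positive delta means risk
was visible in the record before the clinical diagnosis; a negative delta
means the screen only fired afterwards, and such records are deliberately
retained rather than censored.

## The screening rule set

Each encounter is scored on three factor groups:

* **Vitals (physical findings, variable risk):** systolic blood pressure
  ≥ 140 mm Hg (≥ 160 severe), resting heart rate ≥ 110 bpm (≥ 120 severe),
  respiratory rate ≥ 24 (≥ 30 severe), oxygen saturation ≤ 96 % (≤ 94 %
  severe). All comparisons are inclusive exactly as written. An absent
  vital contributes nothing: absence is no information, not normality.
* **Symptoms (variable risk):** unresponsive asthma, chest pain,
  dizziness/syncope, new or worsening headache, palpitations, swelling of
  face or hands, tachypnea, basilar crackles, loud heart murmur — one
  standard hit each; **dyspnea** and **orthopnea** are severe indicators
  on their own.
* **Medical history (static risk):** chronic hypertension, history of
  chemotherapy, history of labor/birth complications, history of heart
  disease, pre-pregnancy BMI ≥ 35, pregestational diabetes, substance
  use — one standard hit each, re-contributed at *every* encounter.

A profile is **red-flag** when any severe indicator is present or when
four or more signs of risk co-occur in a single encounter; otherwise it is
**standard**. There is no cross-encounter accumulation: the count rule is
strictly within-visit.

```{r rule}
classify_encounter(evaluate_vitals(list(sbp = 165)), default_thresholds())$level
```

### Design choices in the rule set

The source criteria list maternal age as a continuous static factor
without a cutpoint, but a continuous factor cannot participate in a count
rule. We use a configurable threshold, defaulting to **35 years**
(advanced maternal age, the conventional obstetric cutpoint); set
`default_thresholds(age_threshold = ...)` to change it. Race and ethnicity
are carried in the profile's demographic snapshot but are *not* risk
signs: scoring them would bake a demographic penalty into a screen whose
stated purpose is to be independent of those attributes, and no threshold
semantics exist for them.

Static hits count toward the ≥ 4 rule by default (`static_in_count =
FALSE` restricts the count to variable factors). Tachypnea-the-symptom and
respiratory-rate-the-vital are distinct findings and contribute two hits
when both fire; `dedupe_tachypnea = TRUE` collapses them. Where the severe
oxygen-saturation value appears alone in narrative summaries, the tabular
criteria give ≤ 96 % as the standard cutpoint, and the tabular version
governs here. When both a severe indicator and the count rule hold, the
recorded trigger is the severe indicator — a reporting convention only,
the level is identical either way.

## Outcome linkage and the delta

Diagnosis and medication codes are matched by case- and dot-insensitive
prefix against a condition code map. The shipped map
(`inst/extdata/codemap.yaml`) is an implementer-supplied ICD-10-CM
convention — the study behind this design did not publish its code lists —
and is fully editable. One deliberate wrinkle: preeclampsia maps to
O14.0/O14.1/O14.9 rather than bare O14, so HELLP (O14.2) maps to exactly
one condition.

Pregnancies are segmented so that linkage never crosses episodes: a birth
encounter closes the current episode, and a pregnancy-related encounter
more than 90 days after that birth (configurable `gap_days`) opens a new
one. The 90-day value is a convention — postpartum follow-up within it
stays with the pregnancy it follows; no published rule exists for
separating consecutive pregnancies in this design.

Per (pregnancy, condition) the outcome event is the *earliest* day on
which any mapped diagnosis or intervention code appears (diagnosis wins a
same-day tie). The anchor profile is policy-selected; the default —
`earliest_red_flag` — is the single most consequential unstated choice in
the procedure, and we surface it as an explicit argument with two
alternatives (`earliest_any`, `latest_before_outcome`). We default to the
earliest red-flag profile because the procedure is framed around *early*
high-risk identification and the linked sample is drawn from red-flag
profiles. All tracked outcomes in an episode link to the same anchor; no
factor-to-condition specificity map is published, so none is imposed by
default.

Patient-level accounting collapses multiple delta records per
(patient, pregnancy) into one unit (`merge_duplicates()`), retaining all
condition-level rows — per-condition tables can therefore sum past 100 %
when patients have several conditions.

## The synthetic cohort generator

No patient-level data are deposited with the study this design follows,
so the package ships a seeded generator
(`generate_cohort(default_sim_config())`) whose defaults *are* the
published study conditions:

* demographic marginals of the final-sample table (e.g. Black 482/604,
  Hispanic 7/604; age bands 18–19, 20–34, 35–40 with weights 1/509/94 of
  604), with demographics drawn independently of outcomes — no joint
  distribution is published, and no fairness conclusion should be drawn
  from the synthetic data;
* exclusion-category fractions of the sample-selection flow
  (11,485/32,409 single-encounter; 14,855/32,409 birth-only-first);
* per-condition prevalence from the per-condition patient counts over the
  6,069 analyzed (the published combined thromboembolism count of 16 is
  split evenly between pulmonary and venous thromboembolism);
* condition-specific lead times `L ~ Normal(mean, sd)` with the published
  per-condition means and SDs (preeclampsia 60.2 (90.9) days, myocardial
  infarction 65.7 (81.4), ...), **untruncated**, so negative deltas arise
  naturally as they did in the study;
* a standard prenatal cadence (care entry week 8; every 28 days to week
  28, 14 days to week 36, weekly to term) — routine visits are implied
  but no schedule is published;
* a second-pregnancy rate of 21/6,069.

The escalation mechanism is invented structure, chosen as the simplest
mechanism producing both standard and red-flag profiles with a
recoverable lead time: each affected patient receives one unscheduled
*onset* encounter at `outcome_day − L` carrying one severe indicator
(uniformly one of SBP ≥ 160, HR ≥ 120, RR ≥ 30, SpO2 ≤ 94, dyspnea,
orthopnea), and scheduled visits from onset to outcome escalate vitals
and symptoms under a linear severity ramp. Outcomes are first coded
between gestational weeks 34 and 39; the onset day is clipped to the
episode (gestational day 14 to birth + 89), which affects under ~3 % of
draws at the default outcome window. Healthy visits carry normal-range
vitals with a low rate of standard-band noise (so that most analyzed
patients accrue at least one risk sign over a pregnancy, as in the study)
but never severe-band noise.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: correlated vital-sign trajectories, missing
vitals, coding idiosyncrasies across source EHRs, demographics–outcome
association, postpartum-onset conditions, or red-flag profiles without
eventual outcomes at the published 1,716-to-620 ratio. Parameter-recovery
results on this cohort validate the *pipeline arithmetic*, not the
clinical performance of any screening algorithm.

## Numerical conventions

* Dates are integer day indices relative to a cohort epoch; all deltas are
  exact integer differences, invariant under a global day shift.
* Rendered percentages and delta statistics round **half-up at one
  decimal**, once, at render time; means and SDs are sample statistics
  (n − 1). A single-record condition has no defined SD and is rendered
  0.0 with an explicit flag. (The printed study tables contain a few
  cells inconsistent with half-up arithmetic — e.g. 16/604 as 2.7 and
  509/604 as 84.4 where half-up gives 2.6 and 84.3; the package
  reproduces arithmetic, not typos.)
* The overall (headline) mean delta averages over condition-level records,
  weighting each patient-condition pair equally; the published weighting
  is unstated, and patient-first averaging is available by summarising
  `merge_duplicates()$records` per patient.
* Exclusion precedence is fixed and documented (single-encounter, then
  birth-only-first, then age) so the ledger is deterministic and its
  categories disjoint; age eligibility (18–40 inclusive) is assessed once
  per patient at the index pregnancy-related visit. The flow ledger keeps
  an `n_excluded_age` category (zero under the default generator, whose
  ages are drawn within 18–40) and re-checks its arithmetic identities at
  render time.

## Problem sizes used in the shipped analyses

The `analysis/` drivers run the full pipeline at the study's initial
extract scale (32,409 patients, ≈ 133,000 encounters; a few seconds per
stage). The packaged recovery checks use 5,000-patient cohorts, at which
~19 % of patients survive the exclusion fractions and ~100 linked records
remain, putting the standard error of the recovered overall mean delta
near 8–9 days; recovery is asserted within three standard errors.

## Worked example

```{r example}
cohort <- generate_cohort(default_sim_config(), n_patients = 2000, seed = 42)
res <- run_screening_pipeline(cohort$patients, cohort$encounters)
res$flow
res$headline$mean
head(res$deltas[, c("condition", "risk_day", "outcome_day", "delta_days")])
```

## Known limitations

The module set implements the *operational* rule set — the published
thresholds and red-flag logic — not the proprietary training that chose
them; no learned weighting or retraining is provided or claimed. Free-text
notes are out of scope (the source design excluded unstructured data),
as are HL7/FHIR/OMOP ingestion and multi-site EHR harmonization. Whether
an "intervention" includes procedures is unstated in the source; only
medication codes are modeled.
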