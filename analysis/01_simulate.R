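#!/usr/bin/env Rscript
# Generate the synthetic obstetric EHR cohort at study scale.
#
# The generator's defaults are calibrated to the published marginals:
# demographic mix, the two exclusion categories of the sample-selection
# flow, per-condition outcome prevalence, and condition-specific lead
# times. Ground truth (planned exclusion category; planted outcome/onset
# days) is written alongside for downstream recovery checks; the pipeline
# itself only ever reads patients.csv and encounters.csv.

library(mcvrisk)
suppressPackageStartupMessages(library(readr))

seed <- 20170101 %% 2^31
out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- default_sim_config()          # n_patients = 32409, study scale
cohort <- generate_cohort(cfg, seed = seed)

write_cohort(cohort$patients, cohort$encounters, out_dir)
write_csv(cohort$truth$patients, file.path(out_dir, "truth_patients.csv"))
write_csv(cohort$truth$outcomes, file.path(out_dir, "truth_outcomes.csv"))

cat(sprintf("Simulated %d patients (%d encounters) with seed %d\n",
            nrow(cohort$patients), nrow(cohort$encounters), seed))
cat(sprintf("Planned exclusions: %d single-encounter, %d birth-only-first\n",
            sum(cohort$truth$patients$category == "single_encounter"),
            sum(cohort$truth$patients$category == "birth_only_first")))
cat(sprintf("Planted outcomes: %d across %d affected patients\n",
            nrow(cohort$truth$outcomes),
            length(unique(cohort$truth$outcomes$patient_id))))
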