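#!/usr/bin/env Rscript
# Apply the inclusion/exclusion criteria and screen every retained
# encounter against the risk thresholds.
#
# Emits the risk profiles (one row per encounter with >= 1 risk sign,
# hits serialized as factor:severity tokens) and the partial flow ledger.

library(mcvrisk)
suppressPackageStartupMessages(library(readr))

in_dir <- "results/cohort"
out_dir <- "results/screening"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cohort <- read_cohort(file.path(in_dir, "patients.csv"),
                      file.path(in_dir, "encounters.csv"))

sel <- apply_inclusion(cohort$patients, cohort$encounters)
cat(sprintf("Of %d patients, %d excluded (single encounter), %d excluded (first record a birth), %d analyzed\n",
            sel$flow$n_initial, sel$flow$n_excluded_single_encounter,
            sel$flow$n_excluded_birth_only_first, sel$flow$n_analyzed))

profiles <- screen_cohort(sel$patients, sel$encounters, default_thresholds())
n_any <- length(unique(profiles$patient_id))
n_red <- sum(profiles$level == "red_flag")
cat(sprintf("%d patients (%0.1f%%) had >= 1 risk sign; %d red-flag profiles among %d profiles\n",
            n_any, 100 * n_any / sel$flow$n_analyzed, n_red, nrow(profiles)))

write_csv(profiles, file.path(out_dir, "profiles.csv"))
write_csv(flow_report(sel$flow), file.path(out_dir, "flow_partial.csv"))
write_csv(sel$patients, file.path(out_dir, "retained_patients.csv"))
write_csv(sel$exclusions, file.path(out_dir, "exclusions.csv"))
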