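#' Run the full screening and lead-time pipeline
#'
#' Convenience wrapper chaining the pipeline stages on an in-memory
#' cohort: inclusion/exclusion ([apply_inclusion()]), pregnancy
#' segmentation ([segment_pregnancies()]), encounter screening
#' ([screen_cohort()]), outcome extraction ([extract_outcomes()]),
#' profile-outcome linkage ([link_profiles()]), duplicate merging
#' ([merge_duplicates()]) and headline statistics ([headline_stats()]),
#' while filling in the cohort flow ledger.
#'
#' @param patients,encounters Cohort tibbles (e.g. from [read_cohort()] or
#'   [generate_cohort()]).
#' @param thresholds Screening thresholds ([default_thresholds()]).
#' @param code_map Condition code map ([default_code_map()]).
#' @param policy Linkage anchor policy (see [link_profiles()]).
#' @param gap_days Pregnancy-episode gap (see [segment_pregnancies()]).
#' @return A list: `flow` ([cohort_flow()]), `profiles`, `outcomes`,
#'   `deltas` (condition-level records), `merged` (see
#'   [merge_duplicates()]), `headline` (see [headline_stats()]),
#'   `retained_patients`.
#' @examples
#' cohort <- generate_cohort(default_sim_config(), n_patients = 300, seed = 2)
#' res <- run_screening_pipeline(cohort$patients, cohort$encounters)
#' res$flow
#' @export
run_screening_pipeline <- function(patients, encounters,
                                   thresholds = default_thresholds(),
                                   code_map = default_code_map(),
                                   policy = "earliest_red_flag",
                                   gap_days = 90) {
  sel <- apply_inclusion(patients, encounters)
  enc <- segment_pregnancies(sel$encounters, gap_days = gap_days)
  profiles <- screen_cohort(sel$patients, enc, thresholds)
  profiles <- attach_episodes(profiles, enc)
  outcomes <- extract_outcomes(enc, code_map)
  deltas <- link_profiles(profiles, outcomes, policy = policy)
  merged <- merge_duplicates(deltas)
  headline <- headline_stats(merged$records)

  flow <- sel$flow
  flow$n_with_any_risk <- length(unique(profiles$patient_id))
  flow$n_red_flag_profiles <- sum(profiles$level == "red_flag")
  flow$n_linked <- merged$n_units
  flow$n_merged_duplicates <- merged$n_merged
  flow$n_final <- merged$n_patients

  list(flow = flow, profiles = profiles, outcomes = outcomes,
       deltas = deltas, merged = merged, headline = headline,
       retained_patients = sel$patients)
}
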