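# Pregnancy segmentation, first-dated outcome extraction, profile-outcome
# linkage with signed deltas, and duplicate-unit merging.

cm <- default_code_map()

test_that("pregnancy segmentation follows the birth + gap rule", {
  # one run ending in a birth -> one episode
  enc <- dplyr::bind_rows(
    make_stream("P1", days = c(0, 28, 56)),
    make_encounter("P1", "B", day = 84, entry_order = 4, is_birth = TRUE)
  )
  seg <- segment_pregnancies(enc)
  expect_true(all(seg$pregnancy_index == 1L))

  # two runs separated by a birth plus a 200-day gap -> two episodes
  enc2 <- dplyr::bind_rows(
    enc,
    make_stream("P1", days = c(284, 312)) |>
      dplyr::mutate(encounter_id = c("E5", "E6"), entry_order = 5:6)
  )
  seg2 <- segment_pregnancies(enc2)
  expect_identical(as.integer(tapply(seg2$pregnancy_index, seg2$day, unique)[
    c("0", "84", "284", "312")]), c(1L, 1L, 2L, 2L))

  # postpartum visit within the gap stays with the closed episode
  enc3 <- dplyr::bind_rows(
    enc,
    make_encounter("P1", "PP", day = 126, entry_order = 5)
  )
  expect_true(all(segment_pregnancies(enc3)$pregnancy_index == 1L))

  # no birth -> one open episode
  expect_true(all(segment_pregnancies(
    make_stream("P1", days = c(0, 28)))$pregnancy_index == 1L))
})

test_that("outcome extraction takes the first dated occurrence per condition", {
  enc <- dplyr::bind_rows(
    make_encounter("P1", "E1", day = 142, entry_order = 2,
                   diagnosis_codes = "O14.0"),
    make_encounter("P1", "E2", day = 150, entry_order = 3,
                   diagnosis_codes = "O14.9"),
    make_encounter("P1", "E0", day = 100, entry_order = 1)
  )
  out <- extract_outcomes(enc, cm)
  expect_identical(nrow(out), 1L)
  expect_identical(out$condition, "preeclampsia")
  expect_identical(out$day, 142L)
  expect_identical(out$source, "diagnosis")

  # no mapped codes -> empty
  expect_identical(nrow(extract_outcomes(make_stream("P1"), cm)), 0L)

  # an earlier mapped intervention (medication) wins, with source recorded
  enc2 <- dplyr::bind_rows(
    make_encounter("P1", "E1", day = 130, entry_order = 1,
                   medication_codes = "RX_PREECLAMPSIA"),
    make_encounter("P1", "E2", day = 142, entry_order = 2,
                   diagnosis_codes = "O14.0")
  )
  out2 <- extract_outcomes(enc2, cm)
  expect_identical(out2$day, 130L)
  expect_identical(out2$source, "intervention")
})

test_that("code matching is case- and dot-insensitive prefix matching", {
  enc <- make_encounter("P1", "E1", day = 10, entry_order = 1,
                        diagnosis_codes = "o14.91;i50.20")
  out <- extract_outcomes(enc, cm)
  expect_setequal(out$condition, c("preeclampsia", "heart_failure"))
  # HELLP (O14.2) maps to hellp only, not preeclampsia
  out2 <- extract_outcomes(
    make_encounter("P1", "E1", day = 10, entry_order = 1,
                   diagnosis_codes = "O14.2"), cm)
  expect_identical(out2$condition, "hellp")
})

profile_row <- function(patient_id, day, level = "red_flag",
                        pregnancy_index = 1L, encounter_id = paste0("E", day)) {
  tibble::tibble(patient_id = patient_id, encounter_id = encounter_id,
                 day = as.integer(day), level = level, trigger = "n/a",
                 n_hits = 1L, hits = "sbp:severe", age_at_visit = 30,
                 race = "Black", pregnancy_index = as.integer(pregnancy_index))
}

outcome_row <- function(patient_id, day, condition = "preeclampsia",
                        pregnancy_index = 1L) {
  tibble::tibble(patient_id = patient_id,
                 pregnancy_index = as.integer(pregnancy_index),
                 condition = condition, day = as.integer(day),
                 source = "diagnosis")
}

test_that("the worked lead-time example: risk day 114, diagnosis day 142, delta 28", {
  d <- link_profiles(profile_row("P1", 114), outcome_row("P1", 142))
  expect_identical(d$delta_days, 28L)
  expect_identical(d$risk_profile_level, "red_flag")
})

test_that("negative deltas are retained", {
  d <- link_profiles(profile_row("P1", 150), outcome_row("P1", 142))
  expect_identical(d$delta_days, -8L)
})

test_that("outcomes with no qualifying profile in their episode yield no record", {
  expect_identical(nrow(link_profiles(profile_row("P1", 10)[0, ],
                                      outcome_row("P1", 142))), 0L)
  # a standard-level profile does not anchor under the red-flag policy
  d <- link_profiles(profile_row("P1", 10, level = "standard"),
                     outcome_row("P1", 142))
  expect_identical(nrow(d), 0L)
  # but it does under earliest_any
  d2 <- link_profiles(profile_row("P1", 10, level = "standard"),
                      outcome_row("P1", 142), policy = "earliest_any")
  expect_identical(d2$delta_days, 132L)
})

test_that("linkage never crosses pregnancy episodes", {
  # profiles only in episode 1, outcome planted in episode 2 -> no record
  d <- link_profiles(profile_row("P1", 10, pregnancy_index = 1L),
                     outcome_row("P1", 400, pregnancy_index = 2L))
  expect_identical(nrow(d), 0L)
})

test_that("anchor policies select the documented profile", {
  profs <- dplyr::bind_rows(
    profile_row("P1", 50, level = "standard", encounter_id = "E50"),
    profile_row("P1", 114, level = "red_flag", encounter_id = "E114"),
    profile_row("P1", 130, level = "red_flag", encounter_id = "E130"),
    profile_row("P1", 160, level = "red_flag", encounter_id = "E160")
  )
  out <- outcome_row("P1", 142)
  expect_identical(link_profiles(profs, out)$risk_day, 114L)
  expect_identical(link_profiles(profs, out, policy = "earliest_any")$risk_day,
                   50L)
  expect_identical(
    link_profiles(profs, out, policy = "latest_before_outcome")$risk_day,
    130L)
  expect_error(link_profiles(profs, out, policy = "nonsense"))
})

test_that("deltas are invariant under a global day shift (translation property)", {
  co <- generate_cohort(default_sim_config(), n_patients = 400, seed = 8)
  res <- run_screening_pipeline(co$patients, co$encounters)
  shifted <- co$encounters
  shifted$day <- shifted$day + 1000L
  res2 <- run_screening_pipeline(co$patients, shifted)
  expect_identical(res$deltas$delta_days, res2$deltas$delta_days)
  expect_identical(res$deltas$patient_id, res2$deltas$patient_id)
})

test_that("recovered deltas equal the planted truth on synthetic cohorts", {
  co <- generate_cohort(default_sim_config(), n_patients = 2500, seed = 12)
  res <- run_screening_pipeline(co$patients, co$encounters)
  j <- dplyr::inner_join(res$deltas, co$truth$outcomes,
                         by = c("patient_id", "pregnancy_index", "condition"))
  # every planted outcome is linked
  expect_identical(nrow(j), nrow(co$truth$outcomes))
  # the overwhelming majority anchor exactly at the planted onset; the
  # rest are earlier chance red flags (noise co-occurring with history)
  expect_gte(mean(j$delta_days == j$expected_delta), 0.95)
  expect_true(all(j$delta_days >= j$expected_delta))
})

test_that("duplicate patient units merge by (patient, pregnancy)", {
  # 620-style: 16 of 620 records are second conditions of the same patient
  recs <- dplyr::bind_rows(
    tibble::tibble(patient_id = sprintf("P%03d", 1:604),
                   pregnancy_index = 1L, condition = "preeclampsia",
                   risk_day = 0L, outcome_day = 10L, delta_days = 10L,
                   risk_profile_level = "red_flag"),
    tibble::tibble(patient_id = sprintf("P%03d", 1:16),
                   pregnancy_index = 1L, condition = "hellp",
                   risk_day = 0L, outcome_day = 12L, delta_days = 12L,
                   risk_profile_level = "red_flag")
  )
  m <- merge_duplicates(recs)
  expect_identical(m$n_units, 620L)
  expect_identical(m$n_merged, 16L)
  expect_identical(m$n_patients, 604L)
  expect_identical(nrow(m$records), 620L)  # condition rows retained

  # no duplicates -> identity
  m0 <- merge_duplicates(recs[1:604, ])
  expect_identical(m0$n_merged, 0L)

  # one patient, three condition records -> one unit, three rows
  r3 <- recs[recs$patient_id == "P001", ]
  r3 <- dplyr::bind_rows(r3, dplyr::mutate(r3[1, ], condition = "eclampsia"))
  m3 <- merge_duplicates(r3)
  expect_identical(m3$n_patients, 1L)
  expect_identical(nrow(m3$records), 3L)
})
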