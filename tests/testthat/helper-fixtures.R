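# In-code fixtures: tiny hand-built patients/encounters tables in the
# interchange schema, used across the unit tests.

make_patient <- function(patient_id = "P1", age = 28, race = "Black",
                         ethnicity = "Non-Hispanic", statics = character(0)) {
  row <- tibble::tibble(patient_id = patient_id,
                        age_at_index = as.integer(age),
                        race = race, ethnicity = ethnicity)
  for (f in static_factors()) row[[f]] <- f %in% statics
  row
}

make_encounter <- function(patient_id = "P1", encounter_id = "E1", day = 0,
                           entry_order = 1, pregnancy_related = TRUE,
                           is_birth = FALSE, sbp = NA, hr = NA, rr = NA,
                           spo2 = NA, symptoms = character(0),
                           diagnosis_codes = "", medication_codes = "") {
  row <- tibble::tibble(
    patient_id = patient_id, encounter_id = encounter_id,
    day = as.integer(day), entry_order = as.integer(entry_order),
    pregnancy_related = pregnancy_related, is_birth = is_birth,
    sbp = as.numeric(sbp), hr = as.numeric(hr), rr = as.numeric(rr),
    spo2 = as.numeric(spo2)
  )
  for (s in symptom_factors()) row[[s]] <- s %in% symptoms
  row$diagnosis_codes <- diagnosis_codes
  row$medication_codes <- medication_codes
  row
}

# n routine encounters for one patient, healthy vitals
make_stream <- function(patient_id = "P1", days = c(0, 28, 56), ...) {
  dplyr::bind_rows(lapply(seq_along(days), function(i) {
    make_encounter(patient_id, sprintf("%s-E%02d", patient_id, i),
                   day = days[i], entry_order = i, ...)
  }))
}
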