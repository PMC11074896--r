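#' Controlled vocabularies for the obstetric EHR model
#'
#' Factor names, condition names and demographic levels used throughout the
#' package. These are exported as functions returning character vectors so
#' that validation code, the synthetic generator and user configuration all
#' agree on one spelling of every term.
#'
#' @name vocab
NULL

#' @describeIn vocab Race levels as recorded (self-identified) in the EHR.
#' @export
race_levels <- function() {
  c("American Indian or Alaska Native", "Asian", "Black", "White",
    "other_unknown")
}

#' @describeIn vocab Ethnicity levels.
#' @export
ethnicity_levels <- function() {
  c("Hispanic", "Non-Hispanic")
}

#' @describeIn vocab Static medical-history risk flags (patient-level,
#'   rarely changing).
#' @export
static_factors <- function() {
  c("chronic_hypertension", "history_chemotherapy",
    "history_birth_complications", "history_heart_disease",
    "prepregnancy_obesity_bmi_ge_35", "pregestational_diabetes",
    "substance_use")
}

#' @describeIn vocab Symptom and physical-finding flags recorded per
#'   encounter (variable risk). Dyspnea and orthopnea are severe (red-flag)
#'   indicators on their own; the rest are standard signs.
#' @export
symptom_factors <- function() {
  c("asthma_unresponsive", "chest_pain", "dizziness_syncope", "dyspnea",
    "headache_new_worsening", "palpitations", "orthopnea",
    "swelling_face_hands", "tachypnea", "basilar_crackles",
    "loud_heart_murmur")
}

#' @describeIn vocab Symptoms that alone trigger a red flag.
#' @export
severe_symptoms <- function() {
  c("dyspnea", "orthopnea")
}

#' @describeIn vocab Vital signs screened per encounter.
#' @export
vital_factors <- function() {
  c("sbp", "hr", "rr", "spo2")
}

#' @describeIn vocab The nine tracked cardiovascular outcome conditions
#'   (thromboembolism split into its pulmonary and venous forms).
#' @export
tracked_conditions <- function() {
  c("preeclampsia", "eclampsia", "cardiomyopathy", "myocardial_infarction",
    "heart_failure", "acute_kidney_disease_failure", "cerebral_infarction",
    "pulmonary_embolism", "venous_thromboembolism", "hellp")
}
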