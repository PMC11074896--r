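#' Encounter-level risk screening engine
#'
#' Implements the operational screening rule set: every encounter is
#' evaluated independently against the configured vital-sign thresholds,
#' symptom flags and static medical-history factors. Any sign of risk
#' yields a risk profile; a profile is *red-flag* (high risk) when a severe
#' indicator is present (HR >= 120, SBP >= 160, RR >= 30, SpO2 <= 94,
#' dyspnea, orthopnea) or when four or more signs of risk co-occur in the
#' single encounter. There is no cross-encounter accumulation: the count
#' rule applies within one visit, and static history re-contributes its
#' hits at every visit.
#'
#' @name risk_engine
NULL

empty_hits <- function() {
  tibble::tibble(
    factor = character(), category = character(), severity = character(),
    observed_value = numeric(), threshold_used = numeric()
  )
}

physical_finding_symptoms <- function() {
  c("basilar_crackles", "loud_heart_murmur")
}

#' Evaluate vital signs against screening thresholds
#'
#' One hit per vital meeting its standard threshold; the hit is severe when
#' the severe threshold is also met. Absent vitals carry no information and
#' produce no hit. Comparisons are inclusive in the configured direction
#' (`ge` for SBP/HR/RR, `le` for SpO2).
#'
#' @param vitals Named list or vector with any of `sbp`, `hr`, `rr`, `spo2`;
#'   missing entries and `NA`s are treated as not measured.
#' @param cfg An [default_thresholds()] configuration.
#' @return A tibble of risk-factor hits with columns `factor`, `category`,
#'   `severity`, `observed_value`, `threshold_used`.
#' @examples
#' evaluate_vitals(list(sbp = 165), default_thresholds())
#' @export
evaluate_vitals <- function(vitals, cfg = default_thresholds()) {
  v <- cfg$vitals
  rows <- lapply(seq_len(nrow(v)), function(i) {
    name <- v$vital[i]
    x <- vitals[[name]]
    if (is.null(x) || is.na(x)) return(NULL)
    meets <- function(thr) {
      if (v$direction[i] == "ge") x >= thr else x <= thr
    }
    if (!meets(v$standard[i])) return(NULL)
    sev <- meets(v$severe[i])
    tibble::tibble(
      factor = name, category = "physical_finding",
      severity = if (sev) "severe" else "standard",
      observed_value = as.numeric(x),
      threshold_used = if (sev) v$severe[i] else v$standard[i]
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty_hits() else out
}

#' Evaluate symptom and physical-finding flags
#'
#' One standard hit per present flag, except the configured severe symptoms
#' (dyspnea and orthopnea by default) which are severe on their own.
#'
#' @param symptoms Character vector of present symptom flags (see
#'   [symptom_factors()]), or a named logical vector/list over that
#'   vocabulary.
#' @inheritParams evaluate_vitals
#' @return A tibble of hits (see [evaluate_vitals()]).
#' @export
evaluate_symptoms <- function(symptoms, cfg = default_thresholds()) {
  if (is.logical(symptoms) || is.list(symptoms)) {
    symptoms <- names(symptoms)[vapply(symptoms, isTRUE, logical(1))]
  }
  symptoms <- as.character(symptoms)
  unknown <- setdiff(symptoms, symptom_factors())
  if (length(unknown) > 0) {
    stop("unknown symptom flag(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(symptoms) == 0) return(empty_hits())
  # stable vocabulary order
  symptoms <- intersect(symptom_factors(), symptoms)
  tibble::tibble(
    factor = symptoms,
    category = ifelse(symptoms %in% physical_finding_symptoms(),
                      "physical_finding", "symptom"),
    severity = ifelse(symptoms %in% cfg$severe_symptoms, "severe", "standard"),
    observed_value = 1,
    threshold_used = NA_real_
  )
}

#' Evaluate static medical-history risk factors
#'
#' One standard hit per present static-history flag, plus an age hit when
#' `age_at_visit` is at or above the configured cutpoint (default 35 years,
#' advanced maternal age). Static factors never trigger a red flag alone;
#' they contribute to the concurrent-sign count.
#'
#' @param patient A one-row patient tibble (see [ehr_model]).
#' @param age_at_visit Age in years at the visit being screened.
#' @inheritParams evaluate_vitals
#' @return A tibble of hits (see [evaluate_vitals()]).
#' @export
evaluate_static <- function(patient, age_at_visit,
                            cfg = default_thresholds()) {
  present <- static_factors()[vapply(static_factors(),
                                     function(f) isTRUE(patient[[f]][1]),
                                     logical(1))]
  rows <- empty_hits()
  if (length(present) > 0) {
    rows <- tibble::tibble(
      factor = present, category = "static", severity = "standard",
      observed_value = 1, threshold_used = NA_real_
    )
  }
  if (!is.na(age_at_visit) && age_at_visit >= cfg$age_threshold) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      factor = "age_ge_threshold", category = "static", severity = "standard",
      observed_value = as.numeric(age_at_visit),
      threshold_used = as.numeric(cfg$age_threshold)
    ))
  }
  rows
}

#' Classify one encounter's hits as a risk profile
#'
#' No hits: no profile (`NULL`). Otherwise the profile is red-flag if and
#' only if any hit is severe, or the number of counted concurrent signs
#' reaches `cfg$count_for_red_flag` (default 4). A severe indicator takes
#' precedence as the recorded trigger when both hold. With
#' `cfg$static_in_count = FALSE` static hits establish a profile but do not
#' count toward the concurrency rule; with `cfg$dedupe_tachypnea = TRUE` a
#' tachypnea flag and an elevated respiratory rate in the same encounter
#' count once.
#'
#' @param hits A hits tibble from the evaluators.
#' @inheritParams evaluate_vitals
#' @return `NULL` when no hits; otherwise a list with elements `level`
#'   (`"standard"` or `"red_flag"`), `trigger` (`"severe_indicator"`,
#'   `"count_ge_4"`, or `"n/a"`), `n_hits`, `n_counted`, and `hits`.
#' @export
classify_encounter <- function(hits, cfg = default_thresholds()) {
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  any_severe <- any(hits$severity == "severe")
  counted <- hits
  if (!cfg$static_in_count) {
    counted <- counted[counted$category != "static", , drop = FALSE]
  }
  n_counted <- nrow(counted)
  if (cfg$dedupe_tachypnea &&
      all(c("tachypnea", "rr") %in% counted$factor)) {
    n_counted <- n_counted - 1L
  }
  red <- any_severe || n_counted >= cfg$count_for_red_flag
  list(
    level = if (red) "red_flag" else "standard",
    trigger = if (any_severe) "severe_indicator"
              else if (red) "count_ge_4" else "n/a",
    n_hits = nrow(hits),
    n_counted = n_counted,
    hits = hits
  )
}

hits_token <- function(hits) {
  paste(paste0(hits$factor, ":", hits$severity), collapse = ";")
}

#' Screen one patient's encounter stream
#'
#' Evaluates each encounter independently, in `(day, entry_order)` order,
#' and emits one risk-profile row per encounter with at least one risk
#' sign. Unsorted input is a contract violation.
#'
#' @param patient One-row patient tibble.
#' @param encounters This patient's encounters, sorted by
#'   `(day, entry_order)`.
#' @inheritParams evaluate_vitals
#' @return A tibble of risk profiles with columns `patient_id`,
#'   `encounter_id`, `day`, `level`, `trigger`, `n_hits`, `hits`
#'   (semicolon-joined `factor:severity` tokens), `age_at_visit`, `race`.
#' @export
screen_patient <- function(patient, encounters, cfg = default_thresholds()) {
  stopifnot(nrow(patient) == 1)
  if (nrow(encounters) > 1) {
    o <- order(encounters$day, encounters$entry_order, method = "radix")
    if (!identical(o, seq_len(nrow(encounters)))) {
      stop("encounters must be sorted by (day, entry_order); see sort_encounters()",
           call. = FALSE)
    }
  }
  age <- patient$age_at_index[1]
  static_hits <- evaluate_static(patient, age, cfg)
  rows <- lapply(seq_len(nrow(encounters)), function(i) {
    enc <- encounters[i, ]
    hits <- dplyr::bind_rows(
      evaluate_vitals(as.list(enc[vital_factors()]), cfg),
      evaluate_symptoms(unlist(enc[symptom_factors()]), cfg),
      static_hits
    )
    prof <- classify_encounter(hits, cfg)
    if (is.null(prof)) return(NULL)
    tibble::tibble(
      patient_id = enc$patient_id, encounter_id = enc$encounter_id,
      day = enc$day, level = prof$level, trigger = prof$trigger,
      n_hits = prof$n_hits, hits = hits_token(prof$hits),
      age_at_visit = as.numeric(age), race = patient$race[1]
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty_profiles() else out
}

empty_profiles <- function() {
  tibble::tibble(
    patient_id = character(), encounter_id = character(), day = integer(),
    level = character(), trigger = character(), n_hits = integer(),
    hits = character(), age_at_visit = numeric(), race = character()
  )
}

#' Screen a whole cohort (vectorized)
#'
#' Equivalent to applying [screen_patient()] to every patient (and tested
#' to agree with it), implemented with vectorized columnwise comparisons so
#' cohorts of tens of thousands of encounters screen in seconds.
#'
#' @param patients,encounters Cohort tibbles ([read_cohort()] /
#'   [generate_cohort()]); encounters need not be pre-sorted.
#' @inheritParams evaluate_vitals
#' @return A risk-profile tibble (see [screen_patient()]).
#' @export
screen_cohort <- function(patients, encounters, cfg = default_thresholds()) {
  enc <- sort_encounters(encounters)
  n <- nrow(enc)
  if (n == 0) return(empty_profiles())

  v <- cfg$vitals
  hit_std <- matrix(FALSE, n, nrow(v), dimnames = list(NULL, v$vital))
  hit_sev <- hit_std
  for (i in seq_len(nrow(v))) {
    x <- enc[[v$vital[i]]]
    if (v$direction[i] == "ge") {
      hit_std[, i] <- !is.na(x) & x >= v$standard[i]
      hit_sev[, i] <- !is.na(x) & x >= v$severe[i]
    } else {
      hit_std[, i] <- !is.na(x) & x <= v$standard[i]
      hit_sev[, i] <- !is.na(x) & x <= v$severe[i]
    }
  }

  sym <- as.matrix(enc[, symptom_factors()])
  sym[is.na(sym)] <- FALSE
  sym_sev <- sym[, cfg$severe_symptoms, drop = FALSE]

  # per-patient static hit matrix, aligned to encounters
  pstat <- as.matrix(patients[, static_factors()])
  pstat[is.na(pstat)] <- FALSE
  age_hit <- !is.na(patients$age_at_index) &
    patients$age_at_index >= cfg$age_threshold
  pidx <- match(enc$patient_id, patients$patient_id)
  if (anyNA(pidx)) {
    stop("encounters reference patient_id(s) absent from patients table",
         call. = FALSE)
  }
  stat <- cbind(pstat, age_ge_threshold = age_hit)[pidx, , drop = FALSE]

  n_vital <- rowSums(hit_std)
  n_sym <- rowSums(sym)
  n_stat <- rowSums(stat)
  n_hits <- n_vital + n_sym + n_stat
  n_counted <- n_vital + n_sym + if (cfg$static_in_count) n_stat else 0
  if (cfg$dedupe_tachypnea) {
    dup <- sym[, "tachypnea"] & hit_std[, "rr"]
    n_counted <- n_counted - as.integer(dup)
  }
  any_severe <- rowSums(hit_sev) + rowSums(sym_sev) > 0
  has_profile <- n_hits > 0
  red <- any_severe | n_counted >= cfg$count_for_red_flag

  idx <- which(has_profile)
  if (length(idx) == 0) return(empty_profiles())

  token_mat <- cbind(
    vapply(seq_len(nrow(v)), function(i) {
      ifelse(hit_sev[idx, i], paste0(v$vital[i], ":severe"),
             ifelse(hit_std[idx, i], paste0(v$vital[i], ":standard"),
                    NA_character_))
    }, character(length(idx))),
    vapply(symptom_factors(), function(s) {
      sev <- s %in% cfg$severe_symptoms
      ifelse(sym[idx, s], paste0(s, ":", if (sev) "severe" else "standard"),
             NA_character_)
    }, character(length(idx))),
    vapply(colnames(stat), function(s) {
      ifelse(stat[idx, s], paste0(s, ":standard"), NA_character_)
    }, character(length(idx)))
  )
  tokens <- apply(token_mat, 1, function(r) paste(r[!is.na(r)], collapse = ";"))

  tibble::tibble(
    patient_id = enc$patient_id[idx],
    encounter_id = enc$encounter_id[idx],
    day = enc$day[idx],
    level = ifelse(red[idx], "red_flag", "standard"),
    trigger = ifelse(any_severe[idx], "severe_indicator",
                     ifelse(red[idx], "count_ge_4", "n/a")),
    n_hits = as.integer(n_hits[idx]),
    hits = tokens,
    age_at_visit = as.numeric(patients$age_at_index[pidx][idx]),
    race = patients$race[pidx][idx]
  )
}
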