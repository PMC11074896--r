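#' Outcome extraction, pregnancy segmentation and lead-time linkage
#'
#' Extracts the first dated occurrence of each tracked cardiovascular
#' condition per pregnancy from diagnosis and medication (intervention)
#' codes, segments each patient's encounter stream into pregnancy
#' episodes, pairs risk profiles with outcomes within the same episode,
#' and computes signed day deltas (`outcome_day - risk_day`; negative when
#' risk was flagged only after the diagnosis). Linkage never crosses
#' pregnancy episodes.
#'
#' @name outcome_linkage
NULL

#' Default condition/symptom code map
#'
#' Maps each tracked condition to ICD-10-CM diagnosis-code prefixes and to
#' intervention (medication) code prefixes. Matching is case-insensitive
#' and dot-insensitive. These prefix lists are implementer-supplied
#' conventions chosen for face validity (the study did not publish its
#' code lists) and are fully editable: load an alternative map from YAML
#' with [read_code_map()]. Preeclampsia deliberately uses the O14.0/O14.1/
#' O14.9 subcategories rather than bare O14 so that HELLP (O14.2) maps to
#' exactly one condition.
#'
#' @return An object of class `mcv_code_map`: a list with elements
#'   `diagnosis` and `intervention`, each a named list of prefix vectors.
#' @export
default_code_map <- function() {
  new_code_map(
    diagnosis = list(
      preeclampsia = c("O140", "O141", "O149"),
      eclampsia = c("O15"),
      cardiomyopathy = c("O903", "I42"),
      myocardial_infarction = c("I21"),
      heart_failure = c("I50"),
      acute_kidney_disease_failure = c("N17"),
      cerebral_infarction = c("I63"),
      pulmonary_embolism = c("I26"),
      venous_thromboembolism = c("I82", "O223"),
      hellp = c("O142")
    ),
    intervention = as.list(stats::setNames(
      paste0("RX_", toupper(tracked_conditions())), tracked_conditions()
    ))
  )
}

new_code_map <- function(diagnosis, intervention) {
  missing <- setdiff(tracked_conditions(), names(diagnosis))
  if (length(missing) > 0) {
    stop("code map lacks diagnosis prefixes for condition(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  norm <- function(lst) lapply(lst, function(p) normalize_code(as.character(p)))
  structure(list(diagnosis = norm(diagnosis),
                 intervention = norm(intervention)),
            class = "mcv_code_map")
}

normalize_code <- function(x) {
  toupper(gsub(".", "", x, fixed = TRUE))
}

#' @rdname default_code_map
#' @param path Path to a YAML file with top-level keys `diagnosis` and
#'   `intervention`, each mapping condition name to a list of prefixes.
#' @export
read_code_map <- function(path) {
  y <- yaml::read_yaml(path)
  new_code_map(diagnosis = y$diagnosis,
               intervention = if (is.null(y$intervention)) list() else y$intervention)
}

#' Segment encounters into pregnancy episodes
#'
#' A birth encounter closes the current episode; a later pregnancy-related
#' encounter more than `gap_days` after that birth opens a new episode.
#' Every encounter belongs to exactly one episode, so postpartum visits
#' within the gap stay with the pregnancy they follow.
#'
#' @param encounters Encounters tibble, sorted per patient by
#'   `(day, entry_order)` (any patients may be mixed; grouping is by
#'   `patient_id`).
#' @param gap_days Days after a birth beyond which a pregnancy-related
#'   encounter starts a new episode (default 90).
#' @return The input with an integer `pregnancy_index` column.
#' @export
segment_pregnancies <- function(encounters, gap_days = 90) {
  enc <- sort_encounters(encounters)
  idx <- integer(nrow(enc))
  pids <- enc$patient_id
  starts <- which(!duplicated(pids))
  ends <- c(starts[-1] - 1L, nrow(enc))
  for (g in seq_along(starts)) {
    ep <- 1L
    last_birth <- NA_integer_
    for (i in seq(starts[g], ends[g])) {
      if (!is.na(last_birth) && isTRUE(enc$pregnancy_related[i]) &&
          enc$day[i] > last_birth + gap_days) {
        ep <- ep + 1L
        last_birth <- NA_integer_
      }
      idx[i] <- ep
      if (isTRUE(enc$is_birth[i])) last_birth <- enc$day[i]
    }
  }
  enc$pregnancy_index <- idx
  enc
}

split_codes <- function(x) {
  strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
}

match_condition <- function(codes, prefixes) {
  # codes already normalized; returns conditions matched by any code
  hit <- vapply(prefixes, function(pfx) {
    any(vapply(pfx, function(p) any(startsWith(codes, p)), logical(1)))
  }, logical(1))
  names(prefixes)[hit]
}

#' Extract first-dated outcome events
#'
#' For every (patient, pregnancy, condition), the earliest day on which
#' any mapped diagnosis or intervention code appears, with the source
#' recorded (`"diagnosis"` wins a same-day tie).
#'
#' @param encounters Encounters with a `pregnancy_index` column (see
#'   [segment_pregnancies()]); the column is added if absent.
#' @param code_map An [default_code_map()] object.
#' @return A tibble of outcome events: `patient_id`, `pregnancy_index`,
#'   `condition`, `day`, `source`.
#' @export
extract_outcomes <- function(encounters, code_map = default_code_map()) {
  stopifnot(inherits(code_map, "mcv_code_map"))
  if (!"pregnancy_index" %in% names(encounters)) {
    encounters <- segment_pregnancies(encounters)
  }
  hits_for <- function(code_col, prefixes, source) {
    has <- !is.na(encounters[[code_col]]) & nzchar(encounters[[code_col]])
    if (!any(has) || length(prefixes) == 0) return(NULL)
    sub <- encounters[has, c("patient_id", "pregnancy_index", "day", code_col)]
    # match each distinct code string once, then join back to the rows
    uniq <- unique(sub[[code_col]])
    matched <- lapply(split_codes(uniq), function(cs) {
      match_condition(normalize_code(cs), prefixes)
    })
    n_match <- lengths(matched)
    if (sum(n_match) == 0) return(NULL)
    lookup <- tibble::tibble(
      code_string = rep(uniq, n_match),
      condition = unlist(matched)
    )
    sub$code_string <- sub[[code_col]]
    joined <- dplyr::inner_join(sub, lookup, by = "code_string",
                                relationship = "many-to-many")
    tibble::tibble(patient_id = joined$patient_id,
                   pregnancy_index = joined$pregnancy_index,
                   condition = joined$condition, day = joined$day,
                   source = source)
  }
  all_hits <- dplyr::bind_rows(
    hits_for("diagnosis_codes", code_map$diagnosis, "diagnosis"),
    hits_for("medication_codes", code_map$intervention, "intervention")
  )
  if (is.null(all_hits) || nrow(all_hits) == 0) {
    return(tibble::tibble(patient_id = character(),
                          pregnancy_index = integer(),
                          condition = character(), day = integer(),
                          source = character()))
  }
  # first dated occurrence per (patient, pregnancy, condition);
  # diagnosis preferred on a same-day tie
  all_hits$src_rank <- ifelse(all_hits$source == "diagnosis", 0L, 1L)
  all_hits <- dplyr::arrange(all_hits, .data$patient_id,
                             .data$pregnancy_index, .data$condition,
                             .data$day, .data$src_rank)
  first <- !duplicated(all_hits[, c("patient_id", "pregnancy_index",
                                    "condition")])
  out <- all_hits[first, c("patient_id", "pregnancy_index", "condition",
                           "day", "source")]
  tibble::as_tibble(out)
}

#' Link risk profiles to outcomes and compute deltas
#'
#' For each outcome event, the delta is computed against the
#' policy-selected anchor profile within the same pregnancy episode:
#' * `"earliest_red_flag"` (default): the earliest red-flag profile;
#' * `"earliest_any"`: the earliest profile of any level;
#' * `"latest_before_outcome"`: the latest profile dated on or before the
#'   outcome day (red-flag or standard).
#'
#' Outcomes with no qualifying profile in their episode yield no record.
#' Negative deltas (risk flagged only after the diagnosis) are retained.
#'
#' @param profiles Risk profiles (see [screen_cohort()]) carrying a
#'   `pregnancy_index` column; join one on via [attach_episodes()] if
#'   needed.
#' @param outcomes Outcome events (see [extract_outcomes()]).
#' @param policy Anchor-selection policy name.
#' @return A tibble of delta records: `patient_id`, `pregnancy_index`,
#'   `condition`, `risk_day`, `outcome_day`, `delta_days`,
#'   `risk_profile_level`.
#' @export
link_profiles <- function(profiles, outcomes,
                          policy = c("earliest_red_flag", "earliest_any",
                                     "latest_before_outcome")) {
  policy <- match.arg(policy)
  if (!"pregnancy_index" %in% names(profiles)) {
    stop("profiles lack a pregnancy_index column; use attach_episodes()",
         call. = FALSE)
  }
  empty <- tibble::tibble(
    patient_id = character(), pregnancy_index = integer(),
    condition = character(), risk_day = integer(), outcome_day = integer(),
    delta_days = integer(), risk_profile_level = character()
  )
  if (nrow(outcomes) == 0 || nrow(profiles) == 0) return(empty)

  cand <- if (policy == "earliest_red_flag") {
    profiles[profiles$level == "red_flag", , drop = FALSE]
  } else {
    profiles
  }
  if (nrow(cand) == 0) return(empty)

  if (policy %in% c("earliest_red_flag", "earliest_any")) {
    anchor <- dplyr::summarise(
      dplyr::group_by(cand, .data$patient_id, .data$pregnancy_index),
      risk_day = min(.data$day),
      risk_profile_level = .data$level[which.min(.data$day)],
      .groups = "drop"
    )
    out <- dplyr::inner_join(outcomes, anchor,
                             by = c("patient_id", "pregnancy_index"))
  } else {
    joined <- dplyr::inner_join(
      outcomes,
      cand[, c("patient_id", "pregnancy_index", "day", "level")],
      by = c("patient_id", "pregnancy_index"),
      relationship = "many-to-many"
    )
    joined <- joined[joined$day.y <= joined$day.x, , drop = FALSE]
    if (nrow(joined) == 0) return(empty)
    joined <- dplyr::arrange(joined, .data$patient_id, .data$pregnancy_index,
                             .data$condition, dplyr::desc(.data$day.y))
    first <- !duplicated(joined[, c("patient_id", "pregnancy_index",
                                    "condition")])
    out <- joined[first, ]
    out <- dplyr::rename(out, day = "day.x", risk_day = "day.y",
                         risk_profile_level = "level")
  }
  tibble::tibble(
    patient_id = out$patient_id,
    pregnancy_index = out$pregnancy_index,
    condition = out$condition,
    risk_day = as.integer(out$risk_day),
    outcome_day = as.integer(out$day),
    delta_days = as.integer(out$day - out$risk_day),
    risk_profile_level = out$risk_profile_level
  )
}

#' Attach pregnancy episode indices to risk profiles
#'
#' Joins `pregnancy_index` from segmented encounters onto a profile table
#' by `(patient_id, encounter_id)`.
#'
#' @param profiles Risk-profile tibble.
#' @param encounters Encounters with `pregnancy_index` (see
#'   [segment_pregnancies()]).
#' @return `profiles` with a `pregnancy_index` column.
#' @export
attach_episodes <- function(profiles, encounters) {
  if (!"pregnancy_index" %in% names(encounters)) {
    encounters <- segment_pregnancies(encounters)
  }
  dplyr::left_join(
    profiles,
    encounters[, c("patient_id", "encounter_id", "pregnancy_index")],
    by = c("patient_id", "encounter_id")
  )
}

#' Collapse duplicate patient units
#'
#' Patient-level counting collapses multiple delta records per
#' (patient, pregnancy) into one patient unit — mirroring the study's
#' combination of patients whose risks tracked to two different outcomes —
#' while retaining every condition-level row for per-condition statistics.
#'
#' @param records Delta records (see [link_profiles()]).
#' @return A list: `records` (unchanged condition-level rows),
#'   `n_units` (pre-merge record count), `n_patients` (distinct
#'   (patient, pregnancy) units), `n_merged` (units removed by merging).
#' @export
merge_duplicates <- function(records) {
  n_units <- nrow(records)
  n_patients <- nrow(unique(records[, c("patient_id", "pregnancy_index")]))
  list(records = records, n_units = n_units, n_patients = n_patients,
       n_merged = n_units - n_patients)
}
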