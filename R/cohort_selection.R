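#' Cohort inclusion/exclusion and flow accounting
#'
#' Applies the study-style inclusion criteria — age 18 to 40 years
#' (inclusive) at the index pregnancy-related visit, more than one
#' pregnancy-related encounter, and a first record that is not a birth
#' without prior pregnancy data — and maintains an auditable
#' CONSORT-style ledger of counts at every stage.
#'
#' Exclusion categories are disjoint: the first matching exclusion wins,
#' in the fixed documented order single-encounter, then birth-only-first,
#' then age. The ledger identities are re-checked whenever a flow is
#' rendered.
#'
#' @name cohort_selection
NULL

#' Construct a cohort flow ledger
#'
#' @param n_initial,n_excluded_single_encounter,n_excluded_birth_only_first,n_excluded_age,n_analyzed,n_with_any_risk,n_red_flag_profiles,n_linked,n_merged_duplicates,n_final
#'   Stage counts; later-stage counts may be `NA` until known.
#' @return An object of class `mcv_flow` (a named list of counts).
#' @export
cohort_flow <- function(n_initial = NA_integer_,
                        n_excluded_single_encounter = NA_integer_,
                        n_excluded_birth_only_first = NA_integer_,
                        n_excluded_age = 0L,
                        n_analyzed = NA_integer_,
                        n_with_any_risk = NA_integer_,
                        n_red_flag_profiles = NA_integer_,
                        n_linked = NA_integer_,
                        n_merged_duplicates = NA_integer_,
                        n_final = NA_integer_) {
  flow <- list(
    n_initial = as.integer(n_initial),
    n_excluded_single_encounter = as.integer(n_excluded_single_encounter),
    n_excluded_birth_only_first = as.integer(n_excluded_birth_only_first),
    n_excluded_age = as.integer(n_excluded_age),
    n_analyzed = as.integer(n_analyzed),
    n_with_any_risk = as.integer(n_with_any_risk),
    n_red_flag_profiles = as.integer(n_red_flag_profiles),
    n_linked = as.integer(n_linked),
    n_merged_duplicates = as.integer(n_merged_duplicates),
    n_final = as.integer(n_final)
  )
  structure(flow, class = "mcv_flow")
}

check_flow <- function(flow) {
  violations <- character(0)
  known <- function(...) all(!is.na(unlist(flow[c(...)])))
  if (known("n_initial", "n_excluded_single_encounter",
            "n_excluded_birth_only_first", "n_excluded_age", "n_analyzed")) {
    lhs <- flow$n_analyzed
    rhs <- flow$n_initial - flow$n_excluded_single_encounter -
      flow$n_excluded_birth_only_first - flow$n_excluded_age
    if (lhs != rhs) {
      violations <- c(violations, sprintf(
        "n_analyzed (%d) != n_initial - exclusions (%d)", lhs, rhs))
    }
  }
  if (known("n_linked", "n_merged_duplicates", "n_final")) {
    if (flow$n_final != flow$n_linked - flow$n_merged_duplicates) {
      violations <- c(violations, sprintf(
        "n_final (%d) != n_linked (%d) - n_merged_duplicates (%d)",
        flow$n_final, flow$n_linked, flow$n_merged_duplicates))
    }
  }
  neg <- names(flow)[!is.na(unlist(flow)) & unlist(flow) < 0]
  if (length(neg) > 0) {
    violations <- c(violations, paste("negative count(s):",
                                      paste(neg, collapse = ", ")))
  }
  violations
}

#' Apply the inclusion/exclusion criteria
#'
#' Retains patients aged `age_range[1]`–`age_range[2]` (inclusive) at the
#' index pregnancy-related visit, with at least two pregnancy-related
#' encounters, whose first record is not a birth without prior pregnancy
#' data. Patients with no encounters at all are counted under the
#' single-encounter (limited-data) category, as are patients with exactly
#' one pregnancy-related encounter.
#'
#' @param patients,encounters Cohort tibbles.
#' @param age_range Inclusive age bounds, default `c(18, 40)`.
#' @return A list: `patients` (retained rows), `encounters` (their
#'   encounters), `flow` (partial [cohort_flow()]), and `exclusions`
#'   (tibble `patient_id`, `category` for every input patient, with
#'   `"retained"` for those kept).
#' @export
apply_inclusion <- function(patients, encounters, age_range = c(18, 40)) {
  enc <- sort_encounters(encounters)
  by_pat <- dplyr::summarise(
    dplyr::group_by(enc, .data$patient_id),
    n_pregnancy = sum(.data$pregnancy_related, na.rm = TRUE),
    first_is_birth = .data$is_birth[1],
    .groups = "drop"
  )
  info <- dplyr::left_join(patients, by_pat, by = "patient_id")
  info$n_pregnancy[is.na(info$n_pregnancy)] <- 0L
  info$first_is_birth[is.na(info$first_is_birth)] <- FALSE

  category <- rep("retained", nrow(info))
  category[info$first_is_birth] <- "birth_only_first"
  # single-encounter checked first: first matching exclusion wins
  category[info$n_pregnancy <= 1] <- "single_encounter"
  ok_age <- !is.na(info$age_at_index) &
    info$age_at_index >= age_range[1] & info$age_at_index <= age_range[2]
  category[category == "retained" & !ok_age] <- "age"

  keep <- category == "retained"
  flow <- cohort_flow(
    n_initial = nrow(patients),
    n_excluded_single_encounter = sum(category == "single_encounter"),
    n_excluded_birth_only_first = sum(category == "birth_only_first"),
    n_excluded_age = sum(category == "age"),
    n_analyzed = sum(keep)
  )
  list(
    patients = patients[keep, , drop = FALSE],
    encounters = enc[enc$patient_id %in% patients$patient_id[keep], ,
                     drop = FALSE],
    flow = flow,
    exclusions = tibble::tibble(patient_id = patients$patient_id,
                                category = category)
  )
}

#' Render the flow ledger
#'
#' Re-checks the arithmetic identities (`n_analyzed` equals the initial
#' count minus all exclusions; `n_final` equals linked minus merged
#' duplicates; no negative counts) and renders the ledger as a tibble
#' suitable for printing or writing to CSV. An inconsistent flow is an
#' error listing every violated identity.
#'
#' @param flow An [cohort_flow()] object.
#' @return A tibble with columns `stage` and `n`.
#' @examples
#' flow_report(cohort_flow(n_initial = 32409,
#'                         n_excluded_single_encounter = 11485,
#'                         n_excluded_birth_only_first = 14855,
#'                         n_analyzed = 6069))
#' @export
flow_report <- function(flow) {
  stopifnot(inherits(flow, "mcv_flow"))
  violations <- check_flow(flow)
  if (length(violations) > 0) {
    stop("inconsistent cohort flow: ", paste(violations, collapse = "; "),
         call. = FALSE)
  }
  tibble::tibble(stage = names(unclass(flow)),
                 n = unname(unlist(unclass(flow))))
}

#' @export
print.mcv_flow <- function(x, ...) {
  cat("Cohort flow ledger\n")
  v <- unlist(unclass(x))
  for (nm in names(v)) {
    cat(sprintf("  %-28s %s\n", nm, ifelse(is.na(v[nm]), "-", v[nm])))
  }
  invisible(x)
}
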