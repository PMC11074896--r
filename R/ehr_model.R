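#' Obstetric EHR interchange model
#'
#' The package consumes flat-file extracts of a longitudinal obstetric EHR:
#' one patients table and one encounters table. All dates are integer day
#' indices relative to an arbitrary cohort epoch (deidentified extracts
#' carry no calendar dates; published results are reported in days).
#'
#' Patients table columns: `patient_id`, `age_at_index` (years at index
#' pregnancy-related visit), `race`, `ethnicity`, plus one logical column
#' per static-history flag (see [static_factors()]).
#'
#' Encounters table columns: `patient_id`, `encounter_id`, `day`,
#' `entry_order` (order of entry into the record system), `pregnancy_related`,
#' `is_birth`, vitals `sbp`/`hr`/`rr`/`spo2` (missing allowed), one logical
#' column per symptom flag (see [symptom_factors()]), and semicolon-joined
#' `diagnosis_codes` and `medication_codes`.
#'
#' @name ehr_model
NULL

patient_columns <- function() {
  c("patient_id", "age_at_index", "race", "ethnicity", static_factors())
}

encounter_columns <- function() {
  c("patient_id", "encounter_id", "day", "entry_order", "pregnancy_related",
    "is_birth", vital_factors(), symptom_factors(),
    "diagnosis_codes", "medication_codes")
}

#' Read a cohort from flat files
#'
#' Reads the patients and encounters tables (CSV, or NDJSON when the file
#' extension is `.ndjson`/`.jsonl`), validates them against the documented
#' schema, and returns encounters sorted per patient by `(day, entry_order)`
#' with a stable sort. A missing required column is a schema error naming
#' the column; an unparseable vital value is downgraded to a missing vital
#' with a row-level warning. Unknown extra columns are tolerated and
#' dropped.
#'
#' @param patients_path,encounters_path File paths.
#' @return A list with elements `patients` and `encounters` (tibbles).
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(patients_path, encounters_path) {
  patients <- read_flat(patients_path)
  encounters <- read_flat(encounters_path)
  patients <- coerce_patients(patients, basename(patients_path))
  encounters <- coerce_encounters(encounters, basename(encounters_path))
  validate_patients(patients)
  validate_encounters(encounters)
  encounters <- sort_encounters(encounters)
  list(patients = patients, encounters = encounters)
}

read_flat <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.(ndjson|jsonl)$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(l) {
      x <- jsonlite::fromJSON(l)
      # arrays of codes are accepted and joined to the CSV convention
      for (cc in c("diagnosis_codes", "medication_codes")) {
        if (cc %in% names(x) && length(x[[cc]]) > 1) {
          x[[cc]] <- paste(x[[cc]], collapse = ";")
        }
      }
      tibble::as_tibble(lapply(x, function(v) if (length(v) == 0) NA else v))
    })
    dplyr::bind_rows(rows)
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE)
  }
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("schema error in ", what, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "")] <- FALSE
  out[is.na(x)] <- FALSE
  as.logical(out)
}

# numeric parse that reports which rows failed instead of failing the read
parse_numeric_lenient <- function(x, col, what) {
  if (is.numeric(x)) return(as.numeric(x))
  chr <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(chr))
  bad <- which(!is.na(chr) & nzchar(chr) & is.na(out))
  if (length(bad) > 0) {
    warning(sprintf("%s: %d unparseable value(s) in column '%s' (rows %s); treated as absent",
                    what, length(bad), col,
                    paste(utils::head(bad, 5), collapse = ",")),
            call. = FALSE)
  }
  out
}

coerce_patients <- function(df, what = "patients") {
  require_columns(df, patient_columns(), what)
  tibble::tibble(
    patient_id = as.character(df$patient_id),
    age_at_index = as.integer(parse_numeric_lenient(df$age_at_index, "age_at_index", what)),
    race = as.character(df$race),
    ethnicity = as.character(df$ethnicity),
    !!!stats::setNames(
      lapply(static_factors(), function(f) parse_logical(df[[f]])),
      static_factors()
    )
  )
}

coerce_encounters <- function(df, what = "encounters") {
  require_columns(df, encounter_columns(), what)
  codes_chr <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  }
  tibble::tibble(
    patient_id = as.character(df$patient_id),
    encounter_id = as.character(df$encounter_id),
    day = as.integer(parse_numeric_lenient(df$day, "day", what)),
    entry_order = as.integer(parse_numeric_lenient(df$entry_order, "entry_order", what)),
    pregnancy_related = parse_logical(df$pregnancy_related),
    is_birth = parse_logical(df$is_birth),
    !!!stats::setNames(
      lapply(vital_factors(), function(v) parse_numeric_lenient(df[[v]], v, what)),
      vital_factors()
    ),
    !!!stats::setNames(
      lapply(symptom_factors(), function(s) parse_logical(df[[s]])),
      symptom_factors()
    ),
    diagnosis_codes = codes_chr(df$diagnosis_codes),
    medication_codes = codes_chr(df$medication_codes)
  )
}

#' Validate cohort tables
#'
#' Checks the model invariants: unique patient ids, non-negative ages,
#' enumerated race/ethnicity, unique `(patient_id, encounter_id)` pairs,
#' finite positive vitals with SpO2 in (0, 100]. Out-of-range vitals are
#' downgraded to missing with a warning rather than rejected.
#'
#' @param patients,encounters Cohort tibbles.
#' @return The (possibly cleaned) input, invisibly for `validate_patients`.
#' @keywords internal
validate_patients <- function(patients) {
  if (anyDuplicated(patients$patient_id) > 0) {
    stop("duplicate patient_id in patients table", call. = FALSE)
  }
  if (any(patients$age_at_index < 0, na.rm = TRUE)) {
    stop("negative age_at_index", call. = FALSE)
  }
  bad_race <- setdiff(unique(patients$race), race_levels())
  if (length(bad_race) > 0) {
    stop("unknown race level(s): ", paste(bad_race, collapse = ", "),
         call. = FALSE)
  }
  bad_eth <- setdiff(unique(patients$ethnicity), ethnicity_levels())
  if (length(bad_eth) > 0) {
    stop("unknown ethnicity level(s): ", paste(bad_eth, collapse = ", "),
         call. = FALSE)
  }
  invisible(patients)
}

validate_encounters <- function(encounters) {
  key <- paste(encounters$patient_id, encounters$encounter_id, sep = "\r")
  if (anyDuplicated(key) > 0) {
    stop("duplicate (patient_id, encounter_id) in encounters table",
         call. = FALSE)
  }
  for (v in vital_factors()) {
    x <- encounters[[v]]
    hi <- if (v == "spo2") 100 else Inf
    bad <- !is.na(x) & (!is.finite(x) | x <= 0 | x > hi)
    if (any(bad)) {
      warning(sprintf("%d out-of-range value(s) in vital '%s' treated as absent",
                      sum(bad), v), call. = FALSE)
      encounters[[v]][bad] <- NA_real_
    }
  }
  invisible(encounters)
}

#' Stable per-patient encounter ordering by (day, entry_order)
#' @param encounters Encounters tibble.
#' @return The tibble sorted; ties preserve input order.
#' @export
sort_encounters <- function(encounters) {
  ord <- order(encounters$patient_id, encounters$day, encounters$entry_order,
               method = "radix")
  encounters[ord, , drop = FALSE]
}

#' Write a cohort to CSV flat files
#'
#' Writes `patients.csv` and `encounters.csv` under `out_dir` in the
#' documented schema. `read_cohort()` of the written files reproduces the
#' input (round-trip identity).
#'
#' @param patients,encounters Cohort tibbles.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_cohort <- function(patients, encounters, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- c(patients = file.path(out_dir, "patients.csv"),
             encounters = file.path(out_dir, "encounters.csv"))
  readr::write_csv(patients[, patient_columns()], paths["patients"],
                   progress = FALSE)
  readr::write_csv(encounters[, encounter_columns()], paths["encounters"],
                   progress = FALSE)
  invisible(paths)
}
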