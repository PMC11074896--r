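#' Study-style summary reporting
#'
#' Demographics table, per-condition delta table and headline lead-time
#' statistics, with an explicit rounding convention: half-up at one
#' decimal, applied once at render time. Means and SDs are sample
#' statistics (n - 1 denominator).
#'
#' @name reporting
NULL

#' Round half-up at a fixed number of decimals
#'
#' Commercial (half-up) rounding, as used in the rendered tables: 0.05
#' rounds to 0.1. Base R's `round()` rounds half to even, which disagrees
#' on exact halves. A small relative epsilon guards against binary
#' representation of decimal halves.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(2.65, 1)  # 2.7 (round() would give 2.6)
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

pct_1dp <- function(n, d) {
  round_half_up(100 * n / d, 1)
}

#' Per-condition delta summary table
#'
#' One row per condition present in the merged delta records, sorted by
#' patient count descending: count, percentage of the final sample
#' (half-up, 1 decimal; percentages may sum past 100 because patients can
#' have multiple conditions), and the sample mean and SD of the signed
#' deltas (1 decimal). A single-record condition has no defined SD and is
#' rendered as 0.0; such rows are flagged in the `sd_undefined` column.
#'
#' @param records Merged delta records (see [merge_duplicates()]).
#' @param n_final Final merged patient count (denominator for
#'   percentages).
#' @return A tibble: `condition`, `n_patients`, `pct_of_final`,
#'   `delta_mean`, `delta_sd`, `sd_undefined`.
#' @export
condition_table <- function(records, n_final) {
  if (is.null(n_final) || is.na(n_final) || n_final <= 0) {
    stop("n_final must be a positive count", call. = FALSE)
  }
  grouped <- dplyr::summarise(
    dplyr::group_by(records, .data$condition),
    n_patients = dplyr::n(),
    delta_mean = mean(.data$delta_days),
    delta_sd = stats::sd(.data$delta_days),
    .groups = "drop"
  )
  grouped$sd_undefined <- is.na(grouped$delta_sd)
  grouped$delta_sd[grouped$sd_undefined] <- 0
  out <- tibble::tibble(
    condition = grouped$condition,
    n_patients = grouped$n_patients,
    pct_of_final = pct_1dp(grouped$n_patients, n_final),
    delta_mean = round_half_up(grouped$delta_mean, 1),
    delta_sd = round_half_up(grouped$delta_sd, 1),
    sd_undefined = grouped$sd_undefined
  )
  out[order(-out$n_patients, out$condition), , drop = FALSE]
}

age_bands <- function() {
  tibble::tibble(band = c("18-19", "20-34", "35-40"),
                 lo = c(18, 20, 35), hi = c(19, 34, 40))
}

#' Demographics table for the final sample
#'
#' Counts and percentages (half-up, 1 decimal) by race, ethnicity and age
#' band (18-19, 20-34, 35-40). Within each single-choice category the
#' unrounded percentages sum to 100.
#'
#' @param patients Patients tibble restricted to the final sample.
#' @return A tibble: `characteristic`, `level`, `n`, `pct`.
#' @export
demographics_table <- function(patients) {
  n <- nrow(patients)
  if (n == 0) stop("empty final sample", call. = FALSE)
  count_level <- function(chr, levels, value) {
    tibble::tibble(
      characteristic = chr, level = levels,
      n = vapply(levels, function(l) sum(value == l), integer(1),
                 USE.NAMES = FALSE)
    )
  }
  ab <- age_bands()
  band_of <- cut(patients$age_at_index, c(ab$lo, max(ab$hi) + 1) - 0.5,
                 labels = ab$band, right = FALSE)
  out <- dplyr::bind_rows(
    count_level("race", race_levels(), patients$race),
    count_level("ethnicity", ethnicity_levels(), patients$ethnicity),
    count_level("age_band", ab$band, as.character(band_of))
  )
  out$pct <- pct_1dp(out$n, n)
  out
}

#' Headline lead-time statistics
#'
#' Overall mean and sample SD of the signed deltas over all
#' condition-level records (each patient-condition pair weighted equally;
#' see the vignette for the weighting discussion), with both the record
#' count and the merged patient count.
#'
#' @param records Delta records (see [merge_duplicates()]).
#' @return A list: `mean`, `sd`, `n_records`, `n_patients`.
#' @export
headline_stats <- function(records) {
  n_rec <- nrow(records)
  n_pat <- nrow(unique(records[, c("patient_id", "pregnancy_index")]))
  list(
    mean = if (n_rec > 0) mean(records$delta_days) else NA_real_,
    sd = if (n_rec > 1) stats::sd(records$delta_days) else NA_real_,
    n_records = n_rec,
    n_patients = n_pat
  )
}
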