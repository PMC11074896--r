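#' Screening threshold configuration
#'
#' The screening rule set is driven entirely by a threshold configuration:
#' per-vital standard and severe (red-flag) cutpoints with their direction
#' of comparison, the set of symptoms that are severe on their own, the
#' maternal-age cutpoint for the static age risk sign, and the number of
#' concurrent risk signs that triggers a red flag.
#'
#' Defaults encode the published clinician-defined criteria:
#' systolic blood pressure >= 140 mm Hg (>= 160 severe), resting heart rate
#' >= 110 bpm (>= 120 severe), respiratory rate >= 24 (>= 30 severe),
#' oxygen saturation <= 96\% (<= 94\% severe), dyspnea and orthopnea severe,
#' and 4 or more concurrent signs of risk in a single encounter.
#' All comparisons are inclusive.
#'
#' Maternal age is recorded continuously but participates in the count rule
#' only at or above `age_threshold` (default 35 years, advanced maternal
#' age); see the package vignette for the rationale.
#'
#' @param count_for_red_flag Number of concurrent risk signs that triggers a
#'   red flag (default 4).
#' @param age_threshold Age in years at or above which age counts as a
#'   static risk sign (default 35).
#' @param static_in_count Should static-history hits count toward the
#'   concurrent-sign rule? Default `TRUE`.
#' @param dedupe_tachypnea If `TRUE`, a tachypnea symptom flag and an
#'   elevated respiratory rate in the same encounter count once. Default
#'   `FALSE`: they are distinct recorded findings and contribute two hits.
#' @return An object of class `mcv_thresholds`: a list with elements
#'   `vitals` (a data frame with columns `vital`, `standard`, `severe`,
#'   `direction`), `severe_symptoms`, `age_threshold`,
#'   `count_for_red_flag`, `static_in_count`, `dedupe_tachypnea`.
#' @examples
#' cfg <- default_thresholds()
#' cfg$vitals
#' @export
default_thresholds <- function(count_for_red_flag = 4L,
                               age_threshold = 35,
                               static_in_count = TRUE,
                               dedupe_tachypnea = FALSE) {
  vitals <- tibble::tibble(
    vital     = c("sbp", "hr", "rr", "spo2"),
    standard  = c(140, 110, 24, 96),
    severe    = c(160, 120, 30, 94),
    direction = c("ge", "ge", "ge", "le")
  )
  new_thresholds(
    vitals = vitals,
    severe_symptoms = severe_symptoms(),
    age_threshold = age_threshold,
    count_for_red_flag = as.integer(count_for_red_flag),
    static_in_count = static_in_count,
    dedupe_tachypnea = dedupe_tachypnea
  )
}

new_thresholds <- function(vitals, severe_symptoms, age_threshold,
                           count_for_red_flag, static_in_count,
                           dedupe_tachypnea) {
  cfg <- list(
    vitals = vitals,
    severe_symptoms = severe_symptoms,
    age_threshold = age_threshold,
    count_for_red_flag = count_for_red_flag,
    static_in_count = static_in_count,
    dedupe_tachypnea = dedupe_tachypnea
  )
  validate_thresholds(cfg)
  structure(cfg, class = "mcv_thresholds")
}

validate_thresholds <- function(cfg) {
  v <- cfg$vitals
  stopifnot(
    is.data.frame(v),
    all(c("vital", "standard", "severe", "direction") %in% names(v)),
    all(v$direction %in% c("ge", "le")),
    cfg$count_for_red_flag >= 1
  )
  # severe must be at least as extreme as standard in the stated direction
  ge <- v$direction == "ge"
  bad <- (ge & v$severe < v$standard) | (!ge & v$severe > v$standard)
  if (any(bad)) {
    stop("severe threshold less extreme than standard for vital(s): ",
         paste(v$vital[bad], collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(cfg$severe_symptoms, symptom_factors())
  if (length(unknown) > 0) {
    stop("unknown severe symptom(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' Read / write a threshold configuration as YAML
#'
#' A full default configuration ships with the package at
#' `system.file("extdata", "thresholds.yaml", package = "mcvrisk")`.
#'
#' @param path Path to a YAML file.
#' @return `read_thresholds()` returns an `mcv_thresholds` object;
#'   `write_thresholds()` returns `path` invisibly.
#' @export
read_thresholds <- function(path) {
  y <- yaml::read_yaml(path)
  new_thresholds(
    vitals = tibble::as_tibble(do.call(rbind.data.frame, lapply(
      y$vitals, function(v) v[c("vital", "standard", "severe", "direction")]
    ))),
    severe_symptoms = as.character(y$severe_symptoms),
    age_threshold = y$age_threshold,
    count_for_red_flag = as.integer(y$count_for_red_flag),
    static_in_count = isTRUE(y$static_in_count),
    dedupe_tachypnea = isTRUE(y$dedupe_tachypnea)
  )
}

#' @rdname read_thresholds
#' @param cfg An `mcv_thresholds` object.
#' @export
write_thresholds <- function(cfg, path) {
  stopifnot(inherits(cfg, "mcv_thresholds"))
  y <- list(
    vitals = lapply(seq_len(nrow(cfg$vitals)), function(i) {
      as.list(cfg$vitals[i, ])
    }),
    severe_symptoms = cfg$severe_symptoms,
    age_threshold = cfg$age_threshold,
    count_for_red_flag = cfg$count_for_red_flag,
    static_in_count = cfg$static_in_count,
    dedupe_tachypnea = cfg$dedupe_tachypnea
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
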