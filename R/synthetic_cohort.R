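#' Synthetic obstetric EHR cohort generation
#'
#' Seeded generator of synthetic longitudinal obstetric cohorts whose
#' statistical structure matches the published study marginals: demographic
#' composition, the two exclusion categories of the sample-selection flow
#' (single pregnancy-related encounter; first record a birth with no
#' pregnancy data), per-condition outcome prevalence with preeclampsia
#' dominant, and condition-specific lead-time distributions between first
#' risk escalation and first recorded diagnosis or intervention. It stands
#' in for the study's health-system data, which are not deposited.
#'
#' The escalation mechanism is deliberately simple, invented structure: an
#' affected patient receives one unscheduled "onset" encounter at
#' `outcome_day - L` (with `L` drawn `Normal(mean, sd)` per condition and
#' not truncated, so negative lead times occur), carrying one severe
#' indicator; scheduled visits between onset and outcome escalate vitals
#' and symptoms with a linear severity ramp. Ground-truth annotations are
#' returned alongside the cohort so linkage and delta recovery are testable
#' without leaking truth into the pipeline inputs.
#'
#' @name synthetic_cohort
NULL

#' Default simulation configuration calibrated to the published study
#'
#' Demographic weights follow the published demographics table (e.g. Black
#' 482/604), exclusion fractions follow the sample-selection flow
#' (11,485/32,409 single-encounter; 14,855/32,409 birth-only-first),
#' per-condition prevalence and lead-time mean/SD follow the published
#' per-condition table (e.g. preeclampsia 547/604 of the final sample,
#' delta 60.2 (SD 90.9) days), and `n_patients` defaults to the study's
#' initial extract size of 32,409. The published combined thromboembolism
#' row (n = 16) is split evenly between pulmonary and venous
#' thromboembolism, both with the published lead time.
#'
#' @return An object of class `mcv_sim_config` (a named list).
#' @examples
#' cfg <- default_sim_config()
#' cfg$lead_time$preeclampsia
#' @export
default_sim_config <- function() {
  cfg <- list(
    seed = 1L,
    n_patients = 32409L,
    demographic_weights = list(
      race = c("American Indian or Alaska Native" = 1 / 604,
               "Asian" = 1 / 604,
               "Black" = 482 / 604,
               "White" = 86 / 604,
               "other_unknown" = 34 / 604),
      ethnicity = c("Hispanic" = 7 / 604, "Non-Hispanic" = 597 / 604),
      age_band = c("18-19" = 1 / 604, "20-34" = 509 / 604,
                   "35-40" = 94 / 604)
    ),
    frac_single_encounter = 11485 / 32409,
    frac_birth_only_first = 14855 / 32409,
    # prevalence among analyzed (retained) patients, from per-condition
    # patient counts over the 6069 analyzed
    condition_prevalence = c(
      preeclampsia = 547 / 6069,
      eclampsia = 9 / 6069,
      cardiomyopathy = 10 / 6069,
      myocardial_infarction = 3 / 6069,
      heart_failure = 5 / 6069,
      acute_kidney_disease_failure = 13 / 6069,
      cerebral_infarction = 4 / 6069,
      pulmonary_embolism = 8 / 6069,
      venous_thromboembolism = 8 / 6069,
      hellp = 7 / 6069
    ),
    lead_time = list(
      preeclampsia = c(mean = 60.2, sd = 90.9),
      eclampsia = c(mean = 46.2, sd = 58.3),
      cardiomyopathy = c(mean = 13.9, sd = 43.9),
      myocardial_infarction = c(mean = 65.7, sd = 81.4),
      heart_failure = c(mean = 13.6, sd = 13.2),
      acute_kidney_disease_failure = c(mean = 25.1, sd = 43.2),
      cerebral_infarction = c(mean = 42.3, sd = 36.8),
      pulmonary_embolism = c(mean = 15.3, sd = 37.7),
      venous_thromboembolism = c(mean = 15.3, sd = 37.7),
      hellp = c(mean = 34.0, sd = 34.8)
    ),
    # standard prenatal schedule: every 28 d to week 28, 14 d to week 36,
    # weekly thereafter (care entry at week 8)
    visit_cadence = tibble::tibble(
      week_from = c(8, 28, 36), week_to = c(28, 36, 40),
      interval_days = c(28, 14, 7)
    ),
    # outcome first coded between gestational weeks 34 and 39
    outcome_window_gd = c(238L, 273L),
    static_prevalence = c(
      chronic_hypertension = 0.08,
      history_chemotherapy = 0.005,
      history_birth_complications = 0.06,
      history_heart_disease = 0.01,
      prepregnancy_obesity_bmi_ge_35 = 0.12,
      pregestational_diabetes = 0.04,
      substance_use = 0.06
    ),
    escalation = list(
      p_symptom = 0.15,          # per standard symptom, per in-window visit
      p_severe_symptom = 0.08,   # dyspnea / orthopnea, per in-window visit
      p_vital = 0.30,            # per vital elevated, per in-window visit
      p_vital_severe_start = 0.15,
      p_vital_severe_end = 0.60, # severity ramp toward the outcome day
      noise_symptom_rate = 0.006,
      noise_vital_rate = 0.012
    ),
    p_medication_same_day = 0.2,
    p_intervention_first = 0.1,  # medication precedes the diagnosis code
    twin_pregnancy_rate = 21 / 6069
  )
  structure(cfg, class = "mcv_sim_config")
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || cfg$n_patients < 1) {
    stop("config error: n_patients must be a positive integer", call. = FALSE)
  }
  probs <- c(cfg$frac_single_encounter, cfg$frac_birth_only_first,
             cfg$condition_prevalence, cfg$static_prevalence,
             cfg$twin_pregnancy_rate, cfg$p_medication_same_day,
             cfg$p_intervention_first)
  if (any(probs < 0 | probs > 1)) {
    stop("config error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$frac_single_encounter + cfg$frac_birth_only_first > 1) {
    stop("config error: exclusion fractions exceed 1", call. = FALSE)
  }
  for (g in names(cfg$demographic_weights)) {
    w <- cfg$demographic_weights[[g]]
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
      stop("config error: demographic weights for '", g,
           "' must be non-negative and sum to 1", call. = FALSE)
    }
  }
  sds <- vapply(cfg$lead_time, function(x) x[["sd"]], numeric(1))
  if (any(sds < 0)) stop("config error: lead_time sd must be >= 0",
                         call. = FALSE)
  invisible(cfg)
}

scheduled_gdays <- function(cadence) {
  gd <- integer(0)
  for (i in seq_len(nrow(cadence))) {
    from <- cadence$week_from[i] * 7
    to <- cadence$week_to[i] * 7
    gd <- c(gd, seq(from, to - 1, by = cadence$interval_days[i]))
  }
  sort(unique(gd))
}

condition_diag_codes <- function() {
  list(
    preeclampsia = c("O14.0", "O14.1", "O14.9"),
    eclampsia = c("O15.0", "O15.9"),
    cardiomyopathy = c("O90.3", "I42.0"),
    myocardial_infarction = c("I21.9"),
    heart_failure = c("I50.9"),
    acute_kidney_disease_failure = c("N17.9"),
    cerebral_infarction = c("I63.9"),
    pulmonary_embolism = c("I26.99"),
    venous_thromboembolism = c("I82.40", "O22.30"),
    hellp = c("O14.2")
  )
}

condition_med_codes <- function() {
  stats::setNames(paste0("RX_", toupper(tracked_conditions())),
                  tracked_conditions())
}

#' Generate a synthetic obstetric EHR cohort
#'
#' Reproducible given the seed (byte-identical output). Returns the two
#' pipeline input tables plus ground-truth annotations that the pipeline
#' never sees: planned exclusion category per patient and, per planted
#' outcome, its first-coded day, the onset (first escalation) day and the
#' drawn lead time.
#'
#' @param config An [default_sim_config()] configuration.
#' @param n_patients,seed Optional overrides of the config values.
#' @return A list with elements `patients`, `encounters` (tibbles in the
#'   interchange schema, encounters sorted), and `truth`: a list of
#'   `patients` (`patient_id`, `category`, `affected`, `n_pregnancies`) and
#'   `outcomes` (`patient_id`, `pregnancy_index`, `condition`,
#'   `outcome_day`, `onset_day`, `lead_drawn`, `expected_delta`).
#' @examples
#' cohort <- generate_cohort(default_sim_config(), n_patients = 200, seed = 7)
#' nrow(cohort$patients)
#' @export
generate_cohort <- function(config = default_sim_config(), n_patients = NULL,
                            seed = NULL) {
  cfg <- config
  if (!is.null(n_patients)) cfg$n_patients <- n_patients
  if (!is.null(seed)) cfg$seed <- seed
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- as.integer(cfg$n_patients)

  ## ---- patients -----------------------------------------------------
  pid <- sprintf("P%06d", seq_len(n))
  w <- cfg$demographic_weights
  race <- sample(names(w$race), n, replace = TRUE, prob = w$race)
  ethnicity <- sample(names(w$ethnicity), n, replace = TRUE,
                      prob = w$ethnicity)
  band <- sample(seq_along(w$age_band), n, replace = TRUE, prob = w$age_band)
  band_lo <- c(18L, 20L, 35L)[band]
  band_hi <- c(19L, 34L, 40L)[band]
  age <- band_lo + as.integer(floor(stats::runif(n) * (band_hi - band_lo + 1L)))

  statics <- vapply(names(cfg$static_prevalence), function(f) {
    stats::rbinom(n, 1, cfg$static_prevalence[[f]]) == 1
  }, logical(n))
  if (n == 1) statics <- matrix(statics, nrow = 1,
                                dimnames = list(NULL, names(cfg$static_prevalence)))

  u <- stats::runif(n)
  category <- ifelse(u < cfg$frac_single_encounter, "single_encounter",
              ifelse(u < cfg$frac_single_encounter + cfg$frac_birth_only_first,
                     "birth_only_first", "retained"))
  e0 <- sample.int(731L, n, replace = TRUE) - 1L

  patients <- tibble::tibble(
    patient_id = pid, age_at_index = age, race = race, ethnicity = ethnicity,
    !!!stats::setNames(
      lapply(static_factors(), function(f) unname(statics[, f])),
      static_factors()
    )
  )

  ## ---- outcomes for retained patients -------------------------------
  ret <- which(category == "retained")
  nr <- length(ret)
  gest <- integer(0)
  truth_outcomes <- tibble::tibble(
    patient_id = character(), pregnancy_index = integer(),
    condition = character(), outcome_day = integer(), onset_day = integer(),
    lead_drawn = numeric(), expected_delta = integer()
  )
  onset_gd <- rep(NA_integer_, nr)
  last_outcome_gd <- rep(NA_integer_, nr)
  twin <- logical(nr)

  if (nr > 0) {
    gest <- pmin(pmax(as.integer(round(stats::rnorm(nr, 277, 8))), 260L), 292L)
    ow <- cfg$outcome_window_gd
    per_cond <- lapply(tracked_conditions(), function(cond) {
      aff <- stats::rbinom(nr, 1, cfg$condition_prevalence[[cond]]) == 1
      k <- sum(aff)
      if (k == 0) return(NULL)
      ogd <- ow[1] + as.integer(floor(stats::runif(k) * (ow[2] - ow[1] + 1L)))
      L <- stats::rnorm(k, cfg$lead_time[[cond]][["mean"]],
                        cfg$lead_time[[cond]][["sd"]])
      tibble::tibble(ridx = which(aff), condition = cond,
                     outcome_gd = ogd, lead_drawn = L)
    })
    planted <- dplyr::bind_rows(per_cond)

    if (nrow(planted) > 0) {
      # birth stays a few days after the last antepartum outcome
      gmax <- tapply(planted$outcome_gd, planted$ridx, max)
      gi <- as.integer(names(gmax))
      gest[gi] <- pmax(gest[gi], as.integer(gmax) + 5L)
      # patient-level onset: earliest (outcome - lead) over conditions,
      # clipped to the pregnancy episode (incl. 90-day postpartum window)
      cand <- tapply(planted$outcome_gd - planted$lead_drawn, planted$ridx, min)
      onset_gd[gi] <- pmin(pmax(as.integer(round(cand)), 14L), gest[gi] + 89L)
      last_outcome_gd[gi] <- as.integer(gmax)

      truth_outcomes <- tibble::tibble(
        patient_id = pid[ret][planted$ridx],
        pregnancy_index = 1L,
        condition = planted$condition,
        outcome_day = e0[ret][planted$ridx] + planted$outcome_gd,
        onset_day = e0[ret][planted$ridx] + onset_gd[planted$ridx],
        lead_drawn = planted$lead_drawn,
        expected_delta = (e0[ret][planted$ridx] + planted$outcome_gd) -
          (e0[ret][planted$ridx] + onset_gd[planted$ridx])
      )
    }
    twin <- stats::runif(nr) < cfg$twin_pregnancy_rate
  }
  affected <- !is.na(onset_gd)

  ## ---- encounter rows ------------------------------------------------
  sched <- scheduled_gdays(cfg$visit_cadence)
  rows <- list()

  add_rows <- function(patient_idx, day, preg, birth, type, epi = 1L,
                       ridx = NA_integer_) {
    tibble::tibble(pidx = patient_idx, day = as.integer(day),
                   pregnancy_related = preg, is_birth = birth,
                   row_type = type, episode = epi, ridx = ridx)
  }

  # excluded: single prenatal visit
  sgl <- which(category == "single_encounter")
  if (length(sgl) > 0) {
    gd1 <- sample(56:200, length(sgl), replace = TRUE)
    rows$single <- add_rows(sgl, e0[sgl] + gd1, TRUE, FALSE, "scheduled")
  }
  # excluded: first record a birth, then a postpartum check
  bo <- which(category == "birth_only_first")
  if (length(bo) > 0) {
    gb <- pmin(pmax(as.integer(round(stats::rnorm(length(bo), 277, 8))), 260L), 292L)
    rows$bo_birth <- add_rows(bo, e0[bo] + gb, TRUE, TRUE, "birth")
    rows$bo_pp <- add_rows(bo, e0[bo] + gb + 42L, TRUE, FALSE, "postpartum")
  }

  if (nr > 0) {
    ridx_all <- seq_len(nr)
    # scheduled prenatal visits
    sched_long <- tibble::tibble(
      ridx = rep(ridx_all, each = length(sched)),
      gd = rep(sched, times = nr)
    )
    sched_long <- sched_long[sched_long$gd < gest[sched_long$ridx], ]
    rows$sched <- add_rows(ret[sched_long$ridx],
                           e0[ret][sched_long$ridx] + sched_long$gd,
                           TRUE, FALSE, "scheduled", ridx = sched_long$ridx)
    rows$birth <- add_rows(ret, e0[ret] + gest, TRUE, TRUE, "birth",
                           ridx = ridx_all)
    rows$pp <- add_rows(ret, e0[ret] + gest + 42L, TRUE, FALSE, "postpartum",
                        ridx = ridx_all)
    # unscheduled onset encounter for affected patients
    aff_i <- which(affected)
    if (length(aff_i) > 0) {
      rows$onset <- add_rows(ret[aff_i], e0[ret][aff_i] + onset_gd[aff_i],
                             TRUE, FALSE, "onset", ridx = aff_i)
    }
    # second (healthy) pregnancy episodes
    tw <- which(twin)
    if (length(tw) > 0) {
      e0_2 <- e0[ret][tw] + gest[tw] + sample(150:400, length(tw), replace = TRUE)
      gest2 <- pmin(pmax(as.integer(round(stats::rnorm(length(tw), 277, 8))), 260L), 292L)
      s2 <- tibble::tibble(k = rep(seq_along(tw), each = length(sched)),
                           gd = rep(sched, times = length(tw)))
      s2 <- s2[s2$gd < gest2[s2$k], ]
      rows$sched2 <- add_rows(ret[tw][s2$k], e0_2[s2$k] + s2$gd, TRUE, FALSE,
                              "scheduled", epi = 2L, ridx = tw[s2$k])
      rows$birth2 <- add_rows(ret[tw], e0_2 + gest2, TRUE, TRUE, "birth",
                              epi = 2L, ridx = tw)
    }
  }

  # outcome code-carrier encounters
  code_rows <- NULL
  if (nrow(truth_outcomes) > 0) {
    k <- nrow(truth_outcomes)
    diag_codes <- condition_diag_codes()
    med_codes <- condition_med_codes()
    dcode <- vapply(truth_outcomes$condition, function(cc) {
      cs <- diag_codes[[cc]]
      cs[sample.int(length(cs), 1)]
    }, character(1))
    int_first <- stats::runif(k) < cfg$p_intervention_first
    med_same <- stats::runif(k) < cfg$p_medication_same_day
    delay <- 1L + as.integer(floor(stats::runif(k) * 7))
    o_pidx <- match(truth_outcomes$patient_id, pid)
    o_ridx <- match(truth_outcomes$patient_id, pid[ret])
    first_row <- add_rows(o_pidx, truth_outcomes$outcome_day, TRUE, FALSE,
                          "outcome", ridx = o_ridx)
    first_row$diagnosis_codes <- ifelse(int_first, "",
                                        unname(dcode))
    first_row$medication_codes <- ifelse(
      int_first | med_same, unname(med_codes[truth_outcomes$condition]), "")
    late <- which(int_first)
    late_row <- NULL
    if (length(late) > 0) {
      late_row <- add_rows(o_pidx[late],
                           truth_outcomes$outcome_day[late] + delay[late],
                           TRUE, FALSE, "outcome", ridx = o_ridx[late])
      late_row$diagnosis_codes <- unname(dcode[late])
      late_row$medication_codes <- ""
    }
    code_rows <- dplyr::bind_rows(first_row, late_row)
  }

  enc <- dplyr::bind_rows(rows)
  if (nrow(enc) > 0) {
    enc$diagnosis_codes <- ifelse(enc$row_type == "birth", "O80",
                                  ifelse(enc$pregnancy_related, "Z34.90", ""))
    enc$medication_codes <- ""
  }
  enc <- dplyr::bind_rows(enc, code_rows)

  ## ---- vitals and symptoms -------------------------------------------
  m <- nrow(enc)
  esc <- cfg$escalation
  # healthy baselines, clamped below the standard thresholds
  sbp <- pmin(round(stats::rnorm(m, 112, 8)), 138)
  hr <- pmin(round(stats::rnorm(m, 80, 8)), 108)
  rr <- pmin(pmax(round(stats::rnorm(m, 16, 2)), 10), 23)
  spo2 <- pmin(pmax(round(stats::rnorm(m, 99, 0.8)), 97), 100)
  symp <- matrix(FALSE, m, length(symptom_factors()),
                 dimnames = list(NULL, symptom_factors()))

  gd_row <- enc$day - e0[enc$pidx]  # gestational day within episode 1
  in_window <- !is.na(enc$ridx) & enc$episode == 1L &
    affected[ifelse(is.na(enc$ridx), 1L, enc$ridx)] &
    !is.na(onset_gd[ifelse(is.na(enc$ridx), 1L, enc$ridx)]) &
    gd_row >= onset_gd[ifelse(is.na(enc$ridx), 1L, enc$ridx)] &
    enc$row_type != "onset"
  in_window[is.na(in_window)] <- FALSE

  # background noise outside the escalation window: standard-band only
  noise_rows <- !in_window & enc$row_type != "onset"
  std_syms <- setdiff(symptom_factors(), severe_symptoms())
  for (s in std_syms) {
    fire <- noise_rows & stats::runif(m) < esc$noise_symptom_rate
    symp[fire, s] <- TRUE
  }
  nb <- which(noise_rows & stats::runif(m) < esc$noise_vital_rate)
  sbp[nb] <- round(stats::runif(length(nb), 140, 159))
  nb <- which(noise_rows & stats::runif(m) < esc$noise_vital_rate)
  hr[nb] <- round(stats::runif(length(nb), 110, 119))
  nb <- which(noise_rows & stats::runif(m) < esc$noise_vital_rate)
  rr[nb] <- round(stats::runif(length(nb), 24, 29))
  nb <- which(noise_rows & stats::runif(m) < esc$noise_vital_rate)
  spo2[nb] <- sample(95:96, length(nb), replace = TRUE)

  # escalation window: linear severity ramp toward the outcome day
  wi <- which(in_window)
  if (length(wi) > 0) {
    r <- enc$ridx[wi]
    span <- pmax(last_outcome_gd[r] - onset_gd[r], 1L)
    t <- pmin(pmax((gd_row[wi] - onset_gd[r]) / span, 0), 1)
    ramp <- 0.3 + 0.7 * t
    for (s in std_syms) {
      symp[wi[stats::runif(length(wi)) < esc$p_symptom * ramp], s] <- TRUE
    }
    for (s in severe_symptoms()) {
      symp[wi[stats::runif(length(wi)) < esc$p_severe_symptom * ramp], s] <- TRUE
    }
    p_sev <- esc$p_vital_severe_start +
      (esc$p_vital_severe_end - esc$p_vital_severe_start) * t
    elevate <- function(cur, std_lo, std_hi, sev_lo, sev_hi) {
      el <- stats::runif(length(wi)) < esc$p_vital * ramp
      sev <- el & stats::runif(length(wi)) < p_sev
      val <- cur[wi]
      val[el] <- round(stats::runif(sum(el), std_lo, std_hi))
      val[sev] <- round(stats::runif(sum(sev), sev_lo, sev_hi))
      cur[wi] <- val
      cur
    }
    sbp <- elevate(sbp, 140, 159, 160, 185)
    hr <- elevate(hr, 110, 119, 120, 140)
    rr <- elevate(rr, 24, 29, 30, 38)
    spo2 <- elevate(spo2, 95, 96, 90, 94)
  }

  # onset encounters carry one severe indicator (the red-flag anchor)
  oi <- which(enc$row_type == "onset")
  if (length(oi) > 0) {
    pick <- sample.int(6L, length(oi), replace = TRUE)
    sbp[oi[pick == 1]] <- round(stats::runif(sum(pick == 1), 160, 185))
    hr[oi[pick == 2]] <- round(stats::runif(sum(pick == 2), 120, 140))
    rr[oi[pick == 3]] <- round(stats::runif(sum(pick == 3), 30, 38))
    spo2[oi[pick == 4]] <- round(stats::runif(sum(pick == 4), 90, 94))
    symp[oi[pick == 5], "dyspnea"] <- TRUE
    symp[oi[pick == 6], "orthopnea"] <- TRUE
    for (s in std_syms) {
      symp[oi[stats::runif(length(oi)) < 0.1], s] <- TRUE
    }
  }

  ## ---- assemble interchange tables -----------------------------------
  ord <- order(enc$pidx, enc$day, method = "radix")
  enc <- enc[ord, ]
  sbp <- sbp[ord]; hr <- hr[ord]; rr <- rr[ord]; spo2 <- spo2[ord]
  symp <- symp[ord, , drop = FALSE]
  entry <- stats::ave(seq_len(nrow(enc)), enc$pidx, FUN = seq_along)

  encounters <- tibble::tibble(
    patient_id = pid[enc$pidx],
    encounter_id = sprintf("%s-e%03d", pid[enc$pidx], entry),
    day = enc$day,
    entry_order = as.integer(entry),
    pregnancy_related = enc$pregnancy_related,
    is_birth = enc$is_birth,
    sbp = as.numeric(sbp), hr = as.numeric(hr), rr = as.numeric(rr),
    spo2 = as.numeric(spo2),
    !!!stats::setNames(
      lapply(symptom_factors(), function(s) unname(symp[, s])),
      symptom_factors()
    ),
    diagnosis_codes = enc$diagnosis_codes,
    medication_codes = enc$medication_codes
  )
  encounters <- sort_encounters(encounters)

  truth_patients <- tibble::tibble(
    patient_id = pid,
    category = category,
    affected = pid %in% truth_outcomes$patient_id,
    n_pregnancies = 1L
  )
  if (nr > 0) {
    truth_patients$n_pregnancies[match(pid[ret][twin], truth_patients$patient_id)] <- 2L
  }

  list(patients = patients, encounters = encounters,
       truth = list(patients = truth_patients, outcomes = truth_outcomes))
}
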