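# Screening rule set: threshold boundaries, severity, the red-flag rule
# ("any severe indicator, or >= 4 concurrent signs"), and encounter
# independence.

cfg <- default_thresholds()

test_that("vital thresholds are inclusive exactly as published (3-point boundary sweep)", {
  # independent truth table: for each vital, classification at
  # threshold - 1 / threshold / threshold + 1 for both cutpoints
  sweep <- list(
    sbp  = list(std = 140, sev = 160, dir = +1),
    hr   = list(std = 110, sev = 120, dir = +1),
    rr   = list(std = 24,  sev = 30,  dir = +1),
    spo2 = list(std = 96,  sev = 94,  dir = -1)
  )
  for (v in names(sweep)) {
    s <- sweep[[v]]
    for (thr in c(s$std, s$sev)) {
      for (off in c(-1, 0, 1)) {
        x <- thr + off
        vit <- stats::setNames(list(x), v)
        hits <- evaluate_vitals(vit, cfg)
        # oracle: inclusive comparison in the stated direction
        meets_std <- if (s$dir > 0) x >= s$std else x <= s$std
        meets_sev <- if (s$dir > 0) x >= s$sev else x <= s$sev
        expected_n <- as.integer(meets_std)
        expect_identical(nrow(hits), expected_n,
                         info = sprintf("%s=%g", v, x))
        if (meets_std) {
          expect_identical(hits$severity,
                           if (meets_sev) "severe" else "standard",
                           info = sprintf("%s=%g", v, x))
        }
      }
    }
  }
})

test_that("published vital examples classify correctly", {
  h <- evaluate_vitals(list(sbp = 165), cfg)
  expect_identical(h$factor, "sbp")
  expect_identical(h$severity, "severe")

  expect_identical(nrow(evaluate_vitals(
    list(sbp = 139, hr = 109, rr = 23, spo2 = 97), cfg)), 0L)

  expect_identical(evaluate_vitals(list(spo2 = 95), cfg)$severity, "standard")
  expect_identical(evaluate_vitals(list(spo2 = 94), cfg)$severity, "severe")
})

test_that("absent vitals carry no information", {
  expect_identical(nrow(evaluate_vitals(list(), cfg)), 0L)
  expect_identical(nrow(evaluate_vitals(list(sbp = NA, hr = NA), cfg)), 0L)
})

test_that("dyspnea and orthopnea are severe; other symptoms standard", {
  h <- evaluate_symptoms(c("dyspnea"), cfg)
  expect_identical(h$severity, "severe")
  expect_identical(nrow(evaluate_symptoms(character(0), cfg)), 0L)
  h2 <- evaluate_symptoms(c("headache_new_worsening", "chest_pain"), cfg)
  expect_identical(nrow(h2), 2L)
  expect_true(all(h2$severity == "standard"))
  expect_error(evaluate_symptoms("nausea", cfg), "nausea")
})

test_that("static history contributes one standard hit per flag plus the age rule", {
  p <- make_patient(statics = c("chronic_hypertension",
                                "pregestational_diabetes"))
  h <- evaluate_static(p, age_at_visit = 28, cfg)
  expect_identical(nrow(h), 2L)
  expect_true(all(h$severity == "standard"))

  expect_identical(nrow(evaluate_static(make_patient(), 25, cfg)), 0L)
  h35 <- evaluate_static(make_patient(age = 35), 35, cfg)
  expect_identical(h35$factor, "age_ge_threshold")
  h34 <- evaluate_static(make_patient(age = 34), 34, cfg)
  expect_identical(nrow(h34), 0L)
})

make_hits <- function(n_standard, n_severe = 0) {
  factors <- c(paste0("f", seq_len(n_standard + n_severe)))
  tibble::tibble(
    factor = factors,
    category = "symptom",
    severity = c(rep("standard", n_standard), rep("severe", n_severe)),
    observed_value = 1, threshold_used = NA_real_
  )
}

test_that("red-flag classification matches the published rule on key cases", {
  r4 <- classify_encounter(make_hits(4), cfg)
  expect_identical(r4$level, "red_flag")
  expect_identical(r4$trigger, "count_ge_4")

  r1s <- classify_encounter(make_hits(0, 1), cfg)
  expect_identical(r1s$level, "red_flag")
  expect_identical(r1s$trigger, "severe_indicator")

  r3 <- classify_encounter(make_hits(3), cfg)
  expect_identical(r3$level, "standard")
  expect_identical(r3$trigger, "n/a")

  expect_null(classify_encounter(make_hits(0), cfg))

  # severe indicator takes precedence as the trigger when both hold
  r5 <- classify_encounter(make_hits(4, 1), cfg)
  expect_identical(r5$trigger, "severe_indicator")
})

test_that("classification agrees with brute-force enumeration over all subsets of an 8-factor universe", {
  # universe: 6 standard factors + 2 severe factors; oracle evaluates the
  # rule "(exists severe) or (count >= 4)" by direct set enumeration
  universe <- tibble::tibble(
    factor = paste0("u", 1:8), category = "symptom",
    severity = c(rep("standard", 6), rep("severe", 2)),
    observed_value = 1, threshold_used = NA_real_
  )
  for (mask in 0:255) {
    sel <- as.logical(bitwAnd(mask, 2^(0:7)))
    hits <- universe[sel, ]
    got <- classify_encounter(hits, cfg)
    n <- sum(sel)
    any_sev <- any(sel[7:8])
    if (n == 0) {
      expect_null(got)
    } else {
      expect_identical(got$level,
                       if (any_sev || n >= 4) "red_flag" else "standard",
                       info = paste("mask", mask))
    }
  }
})

test_that("adding a hit never downgrades a profile (monotonicity)", {
  set.seed(42)
  for (i in 1:50) {
    n_std <- sample(0:5, 1)
    n_sev <- sample(0:2, 1)
    if (n_std + n_sev == 0) next
    base <- make_hits(n_std, n_sev)
    before <- classify_encounter(base, cfg)
    extra <- tibble::tibble(factor = "extra", category = "symptom",
                            severity = sample(c("standard", "severe"), 1),
                            observed_value = 1, threshold_used = NA_real_)
    after <- classify_encounter(dplyr::bind_rows(base, extra), cfg)
    expect_false(is.null(after))
    if (before$level == "red_flag") expect_identical(after$level, "red_flag")
  }
})

test_that("screening a stream profiles each encounter independently", {
  p <- make_patient()
  enc <- make_stream(days = c(0, 28, 56))
  enc$sbp[2] <- 150
  profs <- screen_patient(p, enc, cfg)
  expect_identical(nrow(profs), 1L)
  expect_identical(profs$day, 28L)
  expect_identical(profs$level, "standard")

  # static flags alone = 2, vitals add 2 more at one visit -> red flag by count
  p2 <- make_patient(statics = c("chronic_hypertension", "substance_use"))
  enc2 <- make_stream(days = c(0, 28))
  enc2$sbp[2] <- 145
  enc2$hr[2] <- 112
  profs2 <- screen_patient(p2, enc2, cfg)
  expect_identical(nrow(profs2), 2L)  # statics re-contribute every visit
  expect_identical(profs2$level, c("standard", "red_flag"))
  expect_identical(profs2$trigger[2], "count_ge_4")

  # all-healthy stream -> no profiles
  expect_identical(nrow(screen_patient(make_patient(), make_stream(), cfg)), 0L)

  # unsorted input is a contract violation
  bad <- make_stream(days = c(56, 0, 28))
  expect_error(screen_patient(p, bad, cfg), "sorted")
})

test_that("a given encounter's profile does not depend on the other encounters", {
  p <- make_patient(statics = "chronic_hypertension")
  enc <- make_stream(days = c(0, 28, 56, 84))
  enc$sbp[3] <- 162
  full <- screen_patient(p, enc, cfg)
  target <- full[full$day == 56, ]
  # drop other encounters in several combinations; the day-56 profile is fixed
  for (keep in list(c(3L), c(1L, 3L), c(3L, 4L), c(2L, 3L, 4L))) {
    sub <- enc[sort(keep), ]
    sub$entry_order <- seq_len(nrow(sub))
    got <- screen_patient(p, sub, cfg)
    got_t <- got[got$day == 56, ]
    expect_identical(got_t$level, target$level)
    expect_identical(got_t$hits, target$hits)
  }
})

test_that("vectorized cohort screening agrees with per-patient screening", {
  co <- generate_cohort(default_sim_config(), n_patients = 120, seed = 11)
  fast <- screen_cohort(co$patients, co$encounters, cfg)
  slow <- dplyr::bind_rows(lapply(seq_len(nrow(co$patients)), function(i) {
    p <- co$patients[i, ]
    e <- co$encounters[co$encounters$patient_id == p$patient_id, ]
    screen_patient(p, sort_encounters(e), cfg)
  }))
  fast <- dplyr::arrange(fast, patient_id, day, encounter_id)
  slow <- dplyr::arrange(slow, patient_id, day, encounter_id)
  expect_equal(as.data.frame(fast), as.data.frame(slow))
})

test_that("threshold configuration is validated", {
  expect_error(default_thresholds(count_for_red_flag = 0))
  bad <- default_thresholds()
  bad$vitals$severe[1] <- 130  # less extreme than standard 140
  expect_error(validate_thresholds(bad), "sbp")
})

test_that("thresholds round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_thresholds(default_thresholds(), path)
  got <- read_thresholds(path)
  expect_equal(got$vitals$standard, c(140, 110, 24, 96))
  expect_equal(got$vitals$severe, c(160, 120, 30, 94))
  expect_identical(got$count_for_red_flag, 4L)
})
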