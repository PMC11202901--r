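# Seeded synthetic cohort generator. The generator emulates the structure
# the analysis assumes: shape-typed audiogram pairs for both ears at two
# time points, clinical covariates whose stratum-conditional distributions
# are calibrated to the published recovered / non-recovered contrasts,
# per-feature missingness, and optional planted violations of the
# exclusion cascade. Recovery labels are never stored independently of the
# audiograms: they are always recomputed by the scoring functions.

round5 <- function(x) 5 * round(x / 5)

# 5-dB measurement jitter, bounded to one step.
jitter5 <- function(n) 5 * sample(c(-1L, 0L, 1L), n, replace = TRUE,
                                  prob = c(0.25, 0.5, 0.25))

# Shape templates in 5-dB steps. Offsets are chosen so that (a) the band
# contrasts used by classify_audiogram_shape() survive worst-case +-5 dB
# per-frequency jitter, and (b) the mean over the impaired run sits close
# to the severity target.
shape_templates <- function() {
  list(ascending  = c(5, 5, 0, -10, -15, -20, -25, -30),
       u_shaped   = c(-20, -15, -5, 10, 10, -5, -15, -20),
       descending = c(-30, -25, -20, -15, -10, 0, 5, 5),
       flat       = rep(0, 8),
       deaf       = rep(0, 8))
}

# Feasible severity-target windows (dB, before 5-dB rounding) per shape.
shape_target_window <- function(shape) {
  switch(shape,
         ascending = c(35, 80), descending = c(35, 80), flat = c(35, 80),
         u_shaped = c(40, 80), deaf = c(95, 110))
}

#' Generator configuration
#'
#' Parameters of the synthetic cohort generator. The defaults encode the
#' study conditions the package models: a recovery rate of 37.9%, audiogram
#' shape and severity distributions, clinical covariate distributions and
#' per-feature missingness rates calibrated stratum-by-stratum to the
#' published recovered vs non-recovered comparison (see the methods
#' vignette for the calibration).
#'
#' @param n_patients Number of valid (cascade-passing) patients.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @param recovery_target_rate Probability that a patient is drawn from the
#'   recovered stratum (default 0.379).
#' @param plant_violations Named integer vector of planted exclusion-rule
#'   violations appended to the cohort, with names among
#'   `duplicate_record`, `missing_month1_pta`, `missing_initial_pta`,
#'   `bilateral`, `no_qualifying_run`.
#' @param missingness Named vector of per-feature missing-cell rates in
#'   `[0, 1]`; defaults to [default_missingness()]. Audiometric summary
#'   features and the outcome are never masked.
#' @param zero_gain If `TRUE`, post-treatment audiograms equal the initial
#'   ones (a degenerate no-recovery world used for testing).
#' @param detection A [detection_config()].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_patients = 581, seed = 1,
                             recovery_target_rate = 0.379,
                             plant_violations = c(duplicate_record = 0,
                                                  missing_month1_pta = 0,
                                                  missing_initial_pta = 0,
                                                  bilateral = 0,
                                                  no_qualifying_run = 0),
                             missingness = default_missingness(),
                             zero_gain = FALSE,
                             detection = detection_config()) {
  stopifnot(n_patients >= 0, recovery_target_rate >= 0, recovery_target_rate <= 1,
            all(missingness >= 0), all(missingness <= 1))
  pv <- c(duplicate_record = 0, missing_month1_pta = 0, missing_initial_pta = 0,
          bilateral = 0, no_qualifying_run = 0)
  pv[names(plant_violations)] <- plant_violations
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 recovery_target_rate = recovery_target_rate,
                 plant_violations = pv, missingness = missingness,
                 zero_gain = isTRUE(zero_gain), detection = detection),
            class = "generator_config")
}

#' Default per-feature missingness rates
#'
#' Missing-cell rates used by [generate_cohort()]. Rates for the features
#' with published missingness (triacylglycerol 40.1%, the onset-to-ITDI
#' delay 39.9%, blood urea nitrogen 12.1%, creatinine 9.8%, and the small
#' rates of the comorbidity flags) match the published totals; the
#' remaining laboratory and anthropometric rates are plausible clinical
#' chart-review values. Masking is completely at random.
#'
#' @return Named numeric vector of rates in `[0, 1]`.
#' @export
default_missingness <- function() {
  c(triacylglycerol = 0.401, bun = 0.1205, creatinine = 0.0981,
    onset_to_itdi_days = 0.3993, itdi_duration_category = 0.3993,
    hypertension = 0.009, diabetes = 0.007, mi_angina = 0.009,
    dizziness = 0.005, tinnitus = 0.003,
    total_cholesterol = 0.35, ldl = 0.35,
    hemoglobin = 0.10, wbc = 0.10, neutrophil_pct = 0.10,
    lymphocyte_pct = 0.10, nlr = 0.10, platelet = 0.10,
    pt_sec = 0.15, aptt_sec = 0.15,
    height = 0.05, weight = 0.05, bmi = 0.05,
    sbp = 0.05, dbp = 0.05, smoking_pack_years = 0.05,
    smoking = 0.02, smoking_post_cessation = 0.02,
    stroke = 0.009, hyperlipidemia = 0.009, ckd = 0.009,
    onset_to_treatment_days = 0.02)
}

# Stratum-conditional calibration: audiogram shape mix, severity of the
# affected and unaffected ear, and the clinical covariates with published
# recovered / non-recovered contrasts. "nr" = non-recovery stratum,
# "r" = recovery stratum. Log-normal scale parameters are matched to the
# published median and interquartile range (sigma = log(Q3/Q1) / 1.349).
stratum_calibration <- function() {
  list(
    shape_probs = list(
      nr = c(ascending = 0.0969, u_shaped = 0.0471, descending = 0.3296,
             flat = 0.2244, deaf = 0.3019) / 0.9999,
      r  = c(ascending = 0.2136, u_shaped = 0.1272, descending = 0.2409,
             flat = 0.3773, deaf = 0.0409) / 0.9999),
    pta_affected = list(nr = c(median = 75.63, sigma = log(98.44 / 56.77) / 1.349),
                        r  = c(median = 61.25, sigma = log(77.34 / 48.33) / 1.349)),
    pta_unaffected = list(nr = c(median = 23.13, sigma = log(36.25 / 15.00) / 1.349),
                          r  = c(median = 16.88, sigma = log(23.59 / 10.83) / 1.349)),
    age = list(nr = c(mean = 55, sd = (64 - 47) / 1.349),
               r  = c(mean = 48, sd = (57 - 38.25) / 1.349)),
    triacylglycerol = list(nr = c(median = 99, sigma = log(148 / 66.5) / 1.349),
                           r  = c(median = 82, sigma = log(132 / 56) / 1.349)),
    bun = list(nr = c(median = 15.2, sigma = log(19.58 / 12.4) / 1.349),
               r  = c(median = 13.6, sigma = log(16 / 11.5) / 1.349)),
    creatinine = list(nr = c(median = 0.88, sigma = log(1.04 / 0.71) / 1.349),
                      r  = c(median = 0.83, sigma = log(0.98 / 0.70) / 1.349)),
    onset_to_itdi_days = list(nr = c(median = 6, sigma = log(16 / 3) / 1.349),
                              r  = c(median = 5, sigma = log(8.5 / 2) / 1.349)),
    onset_to_treatment_days = list(nr = c(median = 5, sigma = 0.9),
                                   r  = c(median = 4, sigma = 0.9)),
    binary = list(
      nr = c(hypertension = 0.3629, diabetes = 0.3130, mi_angina = 0.0582,
             dizziness = 0.4211, tinnitus = 0.6371, gender_female = 0.4875),
      r  = c(hypertension = 0.2091, diabetes = 0.2136, mi_angina = 0.014,
             dizziness = 0.1773, tinnitus = 0.7455, gender_female = 0.55))
  )
}

rlnorm_med <- function(n, median, sigma) {
  stats::rlnorm(n, meanlog = log(median), sdlog = sigma)
}

#' Sample an initial affected-ear audiogram of a given shape
#'
#' Builds 8 thresholds in 5-dB steps by adding bounded 5-dB jitter to a
#' fixed per-shape template centred on the severity target. The template
#' contrasts are large enough that [classify_audiogram_shape()] always
#' returns the requested shape, and the construction guarantees a
#' qualifying impaired run under the default detection rule.
#'
#' @param shape One of [audiogram_shapes()].
#' @param severity_target_db Target mean threshold (dB) over the impaired
#'   run; must lie in the shape's feasible window (35-80 dB for ascending,
#'   descending and flat, 40-80 for u-shaped, 95-110 for deaf).
#' @return Numeric vector of 8 thresholds.
#' @export
sample_initial_audiogram <- function(shape, severity_target_db) {
  shape <- match.arg(shape, audiogram_shapes())
  w <- shape_target_window(shape)
  if (!is.finite(severity_target_db) || severity_target_db < w[1] ||
      severity_target_db > w[2]) {
    stop(sprintf("infeasible severity target %.1f dB for shape '%s' (feasible: %g-%g)",
                 severity_target_db, shape, w[1], w[2]), call. = FALSE)
  }
  t0 <- round5(severity_target_db)
  t0 <- min(max(t0, w[1]), w[2])
  x <- t0 + shape_templates()[[shape]] + jitter5(8)
  pmin(pmax(x, -10), 120)
}

#' Sample a post-treatment affected-ear audiogram
#'
#' Draws the one-month audiogram from the initial one and a latent
#' prognosis score in `[0, 1]`. Higher prognosis yields larger hearing
#' gain. Patients above the `1 - recovery_rate` quantile of the prognosis
#' score end in a recovered grade (complete or partial) over their
#' impaired run, the rest in a non-recovered grade (slight or none); the
#' per-frequency construction keeps the run mean inside a class-safe
#' window so the planted grade always survives 5-dB quantisation.
#' Thresholds never exceed the initial value by more than 5 dB and are
#' floored at -10 dB.
#'
#' @param initial Initial affected-ear audiogram (length-8 numeric).
#' @param prognosis Latent prognosis score in `[0, 1]`.
#' @param recovery_rate Stratum cut point (default 0.379).
#' @param config A [detection_config()]; the initial audiogram must
#'   contain a qualifying run.
#' @param zero_gain If `TRUE`, return the initial audiogram unchanged.
#' @return Numeric vector of 8 thresholds.
#' @export
sample_posttreatment_audiogram <- function(initial, prognosis,
                                           recovery_rate = 0.379,
                                           config = detection_config(),
                                           zero_gain = FALSE) {
  if (zero_gain) return(initial)
  rng <- detect_impaired_range(initial, config)
  if (is.null(rng)) stop("initial audiogram has no qualifying run", call. = FALSE)
  idx <- rng$start:(rng$start + rng$length - 1L)
  init_mean <- mean(initial[idx])
  recovered <- prognosis > (1 - recovery_rate)
  out <- initial

  if (recovered) {
    u <- (prognosis - (1 - recovery_rate)) / max(recovery_rate, 1e-9)
    # complete always feasible; partial needs enough initial loss for the
    # gain requirement to survive 5-dB quantisation
    win <- if (init_mean < 50 || stats::runif(1) < 0.4) {
      c(-5, 25)
    } else {
      c(27.5, min(42.5, init_mean - 17.5))
    }
  } else {
    u <- prognosis / max(1 - recovery_rate, 1e-9)
    if (init_mean >= 72.5 && stats::runif(1) < 0.35) {
      win <- c(47.5, min(72.5, init_mean - 17.5))   # slight
    } else {
      # none: small per-frequency gains relative to the initial thresholds,
      # so the run mean stays above the complete-recovery cut and the gain
      # below the recovery-granting cut
      gain_target <- if (init_mean <= 37.5) 0 else u * 10
      g <- if (gain_target == 0) 0 else {
        round5(pmin(pmax(gain_target + 2 * stats::rnorm(length(idx)), 0), 10))
      }
      out[idx] <- initial[idx] - g
      win <- NULL
    }
  }
  if (!is.null(win)) {
    target <- win[2] - u * (win[2] - win[1])  # better prognosis -> lower mean
    out[idx] <- round5(target) + jitter5(length(idx))
    # shift the whole run in 5-dB steps until its mean is inside the window
    for (k in 1:12) {
      m <- mean(out[idx])
      if (m < win[1]) out[idx] <- out[idx] + 5
      else if (m > win[2]) out[idx] <- out[idx] - 5
      else break
    }
  }
  # outside the run: modest prognosis-scaled improvement, never worse than
  # the initial threshold plus 5 dB of test-retest noise
  rest <- setdiff(seq_along(initial), idx)
  if (length(rest)) {
    gain_out <- pmax(0, u * 10 + 5 * stats::rnorm(length(rest)))
    out[rest] <- pmin(round5(initial[rest] - gain_out), initial[rest] + 5)
  }
  pmax(out, -10)
}

#' Sample the clinical covariates of a stratum
#'
#' Draws the non-audiometric features of `n` patients conditional on the
#' prognosis stratum. Covariates with published stratum contrasts (age,
#' triacylglycerol, blood urea nitrogen, creatinine, treatment delays,
#' hypertension, diabetes, myocardial infarction or angina, dizziness,
#' tinnitus, gender) follow the calibrated stratum distributions;
#' covariates without published contrasts are drawn from pooled clinical
#' ranges. Body-mass index and the neutrophil-lymphocyte ratio are derived
#' from their parents before any masking.
#'
#' @param n Number of patients to draw.
#' @param recovered Logical: draw from the recovered stratum?
#' @return A data.frame of clinical features (no audiometric columns).
#' @export
sample_clinical_features <- function(n, recovered) {
  cal <- stratum_calibration()
  s <- if (recovered) "r" else "nr"
  b <- cal$binary[[s]]
  rb <- function(p) stats::rbinom(n, 1, p)

  age <- round(pmin(pmax(stats::rnorm(n, cal$age[[s]]["mean"], cal$age[[s]]["sd"]), 18), 92))
  height <- round(stats::rnorm(n, 164, 8.5), 1)
  weight <- round(stats::rnorm(n, 65, 12), 1)
  weight <- pmax(weight, 35)
  bmi <- round(weight / (height / 100)^2, 2)

  smoke3 <- sample(c("non", "smoker", "post"), n, replace = TRUE,
                   prob = c(0.66, 0.22, 0.12))
  smoking <- as.integer(smoke3 == "smoker")
  smoking_post <- as.integer(smoke3 == "post")
  pack_years <- ifelse(smoke3 == "non", 0,
                       round(rlnorm_med(n, 15, 0.7), 1))

  neut <- pmin(pmax(stats::rnorm(n, 58, 9), 20), 90)
  lymph <- pmin(pmax(stats::rnorm(n, 32, 8), 5), 70)

  onset_tx <- pmin(round(rlnorm_med(n, cal$onset_to_treatment_days[[s]]["median"],
                                    cal$onset_to_treatment_days[[s]]["sigma"])), 90)
  onset_itdi <- pmin(round(rlnorm_med(n, cal$onset_to_itdi_days[[s]]["median"],
                                      cal$onset_to_itdi_days[[s]]["sigma"])), 120)
  itdi_cat <- cut(onset_itdi, c(-1, 3, 7, 12, Inf), labels = FALSE)

  tx <- sample(c("combined", "systemic", "itdi"), n, replace = TRUE,
               prob = c(0.68, 0.22, 0.10))

  data.frame(
    age = age, height = height, weight = weight,
    gender_female = rb(b["gender_female"]),
    bmi = bmi, smoking_pack_years = pack_years,
    sbp = round(stats::rnorm(n, 125, 15)), dbp = round(stats::rnorm(n, 78, 10)),
    smoking = smoking, smoking_post_cessation = smoking_post,
    hypertension = rb(b["hypertension"]), diabetes = rb(b["diabetes"]),
    stroke = rb(0.03), dizziness = rb(b["dizziness"]),
    tinnitus = rb(b["tinnitus"]), hyperlipidemia = rb(0.15),
    ckd = rb(0.03), mi_angina = rb(b["mi_angina"]),
    total_cholesterol = round(rlnorm_med(n, 190, 0.236), 1),
    ldl = round(rlnorm_med(n, 110, 0.317), 1),
    triacylglycerol = round(rlnorm_med(n, cal$triacylglycerol[[s]]["median"],
                                       cal$triacylglycerol[[s]]["sigma"]), 1),
    hemoglobin = round(stats::rnorm(n, 14.2, 1.5), 1),
    bun = round(rlnorm_med(n, cal$bun[[s]]["median"], cal$bun[[s]]["sigma"]), 2),
    creatinine = round(rlnorm_med(n, cal$creatinine[[s]]["median"],
                                  cal$creatinine[[s]]["sigma"]), 2),
    wbc = round(rlnorm_med(n, 6.8, 0.331), 2),
    neutrophil_pct = round(neut, 1), lymphocyte_pct = round(lymph, 1),
    nlr = round(neut / lymph, 2),
    platelet = round(stats::rnorm(n, 250, 60)),
    pt_sec = round(stats::rnorm(n, 11.5, 0.9), 1),
    aptt_sec = round(stats::rnorm(n, 30.5, 3.2), 1),
    onset_to_treatment_days = onset_tx,
    onset_to_itdi_days = onset_itdi,
    hospitalization = rb(0.72),
    affected_side_left = rb(0.5),
    itdi_duration_category = itdi_cat,
    onset_month = sample(1:12, n, replace = TRUE),
    tx_systemic = as.integer(tx == "systemic"),
    tx_itdi = as.integer(tx == "itdi"),
    tx_combined = as.integer(tx == "combined"),
    stringsAsFactors = FALSE
  )
}

#' Inject completely-at-random missingness into cohort features
#'
#' Masks cells of the named features at the configured rates. Audiogram
#' threshold columns, audiometric summary features (`pta_*`, `severity_*`,
#' `run_length`, shape indicators) and outcome columns are never masked,
#' whatever the rates say.
#'
#' @param cohort A cohort data.frame.
#' @param rates Named numeric vector of per-feature rates in `[0, 1]`.
#' @return The cohort with masked cells set to `NA`.
#' @export
inject_missingness <- function(cohort, rates = default_missingness()) {
  if (any(rates < 0 | rates > 1)) {
    stop("missingness rates must lie in [0, 1]", call. = FALSE)
  }
  protected <- c(grep("^ac_", names(cohort), value = TRUE),
                 "pta_avg_affected", "pta_avg_unaffected",
                 "severity_affected", "severity_unaffected", "run_length",
                 paste0("shape_", audiogram_shapes()),
                 grep("^recovered|^class_", names(cohort), value = TRUE))
  for (v in names(rates)) {
    if (!v %in% names(cohort) || v %in% protected) next
    mask <- stats::runif(nrow(cohort)) < rates[[v]]
    cohort[[v]][mask] <- NA
  }
  cohort
}

#' Generate a synthetic cohort
#'
#' Assembles a complete cohort: latent prognosis scores, stratum-typed
#' audiograms for both ears at both time points, the 50 clinical and
#' audiometric features, per-feature missingness, recovery labels computed
#' by the scoring functions (never planted directly), and optionally
#' appended patients violating specific exclusion rules. The output is a
#' deterministic function of the configuration.
#'
#' @param config A [generator_config()].
#' @return A data.frame of class `ppsc_cohort` with one row per patient:
#'   `patient_id`, `plant` (which exclusion rule the row was built to
#'   violate, `"none"` for valid patients), `bilateral`, the 32 threshold
#'   columns `ac_<aff|una>_<freq>_<t0|t1>`, the 50 features of
#'   [feature_schema()], and the scored outcomes `class_ppsc`,
#'   `recovered_ppsc`, `class_traditional`, `recovered_traditional`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(config$seed)

  n <- config$n_patients
  rate <- config$recovery_target_rate
  cal <- stratum_calibration()

  prognosis <- stats::runif(n)
  recovered_intent <- prognosis > (1 - rate)

  make_patients <- function(idx, recov) {
    n_s <- length(idx)
    if (!n_s) return(NULL)
    s <- if (recov) "r" else "nr"
    shapes <- sample(audiogram_shapes(), n_s, replace = TRUE,
                     prob = cal$shape_probs[[s]][audiogram_shapes()])
    feats <- sample_clinical_features(n_s, recov)
    aud <- matrix(NA_real_, n_s, 32)
    derived <- vector("list", n_s)
    for (i in seq_len(n_s)) {
      w <- shape_target_window(shapes[i])
      p <- cal$pta_affected[[s]]
      tgt <- min(max(rlnorm_med(1, p["median"], p["sigma"]), w[1]), w[2])
      aff0 <- sample_initial_audiogram(shapes[i], tgt)
      aff1 <- sample_posttreatment_audiogram(aff0, prognosis[idx[i]],
                                             recovery_rate = rate,
                                             config = config$detection,
                                             zero_gain = config$zero_gain)
      pu <- cal$pta_unaffected[[s]]
      una_level <- min(max(rlnorm_med(1, pu["median"], pu["sigma"]), -5), 60)
      una0 <- pmin(pmax(round5(una_level) + jitter5(8), -10), 120)
      una1 <- pmin(pmax(una0 + jitter5(8), -10), 120)
      aud[i, ] <- c(aff0, aff1, una0, una1)
      derived[[i]] <- derive_audiometric_features(aff0, una0, config$detection)
    }
    colnames(aud) <- c(audiogram_cols("aff", "t0"), audiogram_cols("aff", "t1"),
                       audiogram_cols("una", "t0"), audiogram_cols("una", "t1"))
    der <- data.frame(
      pta_avg_affected = vapply(derived, `[[`, 0, "pta_avg_affected"),
      pta_avg_unaffected = vapply(derived, `[[`, 0, "pta_avg_unaffected"),
      severity_affected = vapply(derived, `[[`, 0L, "severity_affected"),
      severity_unaffected = vapply(derived, `[[`, 0L, "severity_unaffected"),
      run_length = vapply(derived, `[[`, 0L, "run_length"))
    for (sh in audiogram_shapes()) {
      der[[paste0("shape_", sh)]] <- vapply(derived, `[[`, 0L, paste0("shape_", sh))
    }
    cbind(data.frame(row_idx = idx, plant = "none", bilateral = 0L,
                     stringsAsFactors = FALSE),
          as.data.frame(aud), feats, der)
  }

  valid <- rbind(make_patients(which(!recovered_intent), FALSE),
                 make_patients(which(recovered_intent), TRUE))
  valid <- valid[order(valid$row_idx), , drop = FALSE]
  valid$row_idx <- NULL
  valid <- inject_missingness(valid, config$missingness)

  plants <- make_plants(valid, config)
  cohort <- rbind(valid, plants)
  rownames(cohort) <- NULL
  cohort <- cbind(patient_id = sprintf("P%05d", seq_len(nrow(cohort))), cohort,
                  stringsAsFactors = FALSE)

  # score the valid patients; planted rows may be unscorable by design
  scorable <- cohort$plant %in% c("none", "bilateral", "duplicate_record")
  cohort$class_ppsc <- NA_character_
  cohort$recovered_ppsc <- NA_integer_
  cohort$class_traditional <- NA_character_
  cohort$recovered_traditional <- NA_integer_
  if (any(scorable)) {
    sc <- score_cohort(cohort[scorable, , drop = FALSE], "both",
                       config = config$detection)
    pp <- sc[sc$variant == "ppsc", ]
    tr <- sc[sc$variant == "traditional", ]
    cohort$class_ppsc[scorable] <- pp$class
    cohort$recovered_ppsc[scorable] <- as.integer(pp$recovered)
    cohort$class_traditional[scorable] <- tr$class
    cohort$recovered_traditional[scorable] <- as.integer(tr$recovered)
  }
  class(cohort) <- c("ppsc_cohort", "data.frame")
  cohort
}

# Build the planted exclusion-rule violations. Each plant violates exactly
# the rule it is labelled with (given the cascade's sequential order).
make_plants <- function(valid, config) {
  pv <- config$plant_violations
  total <- sum(pv)
  if (total == 0 || nrow(valid) == 0) return(valid[0, , drop = FALSE])
  out <- vector("list", total)
  k <- 0L
  base_row <- function() {
    # a fresh valid-like patient, drawn from the pooled strata
    recov <- stats::runif(1) < config$recovery_target_rate
    cal <- stratum_calibration()
    s <- if (recov) "r" else "nr"
    shape <- sample(audiogram_shapes(), 1,
                    prob = cal$shape_probs[[s]][audiogram_shapes()])
    w <- shape_target_window(shape)
    tgt <- min(max(rlnorm_med(1, cal$pta_affected[[s]]["median"],
                              cal$pta_affected[[s]]["sigma"]), w[1]), w[2])
    aff0 <- sample_initial_audiogram(shape, tgt)
    aff1 <- sample_posttreatment_audiogram(aff0, stats::runif(1),
                                           recovery_rate = config$recovery_target_rate,
                                           config = config$detection)
    una0 <- pmin(pmax(round5(20) + jitter5(8), -10), 120)
    una1 <- pmin(pmax(una0 + jitter5(8), -10), 120)
    feats <- sample_clinical_features(1, recov)
    der <- derive_audiometric_features(aff0, una0, config$detection)
    row <- data.frame(plant = "none", bilateral = 0L, stringsAsFactors = FALSE)
    aud <- c(aff0, aff1, una0, una1)
    names(aud) <- c(audiogram_cols("aff", "t0"), audiogram_cols("aff", "t1"),
                    audiogram_cols("una", "t0"), audiogram_cols("una", "t1"))
    row <- cbind(row, as.data.frame(as.list(aud)), feats,
                 data.frame(pta_avg_affected = der$pta_avg_affected,
                            pta_avg_unaffected = der$pta_avg_unaffected,
                            severity_affected = der$severity_affected,
                            severity_unaffected = der$severity_unaffected,
                            run_length = der$run_length))
    for (sh in audiogram_shapes()) row[[paste0("shape_", sh)]] <- der[[paste0("shape_", sh)]]
    row[, names(valid)]
  }
  add <- function(row, rule) {
    k <<- k + 1L
    row$plant <- rule
    out[[k]] <<- row
  }
  for (i in seq_len(pv["duplicate_record"])) {
    add(valid[sample(nrow(valid), 1), , drop = FALSE], "duplicate_record")
  }
  for (i in seq_len(pv["missing_month1_pta"])) {
    row <- base_row()
    miss <- sample(audiogram_cols("aff", "t1"), 2)
    row[, miss] <- NA_real_
    add(row, "missing_month1_pta")
  }
  for (i in seq_len(pv["missing_initial_pta"])) {
    row <- base_row()
    ear <- if (stats::runif(1) < 0.5) "aff" else "una"
    row[, sample(audiogram_cols(ear, "t0"), 1)] <- NA_real_
    add(row, "missing_initial_pta")
  }
  for (i in seq_len(pv["bilateral"])) {
    row <- base_row()
    row$bilateral <- 1L
    add(row, "bilateral")
  }
  for (i in seq_len(pv["no_qualifying_run"])) {
    row <- base_row()
    # isolated impaired frequencies only: no 3-contiguous run at >= 30 dB
    aff0 <- c(35, 25, 20, 35, 25, 20, 35, 25) + jitter5(8) * 0
    row[, audiogram_cols("aff", "t0")] <- aff0
    row[, audiogram_cols("aff", "t1")] <- aff0
    add(row, "no_qualifying_run")
  }
  do.call(rbind, out)
}

#' Write a cohort to CSV
#'
#' Plain comma-separated UTF-8 with a header row; missing cells are empty.
#'
#' @param cohort A cohort data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort CSV
#'
#' @param path Path to a CSV written by [write_cohort()] (or following the
#'   same schema: one row per patient, `ac_<ear>_<freq>_<t0|t1>` threshold
#'   columns, empty cell = missing).
#' @return A `ppsc_cohort` data.frame.
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c(audiogram_cols("aff", "t0"), audiogram_cols("aff", "t1"))
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop("cohort file lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  class(x) <- c("ppsc_cohort", "data.frame")
  x
}
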