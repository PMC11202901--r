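test_that("cohort generation is byte-identical under a fixed seed", {
  cfg <- generator_config(n_patients = 40, seed = 123,
                          plant_violations = c(bilateral = 2))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(generate_cohort(cfg), f1)
  write_cohort(generate_cohort(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # round trip through CSV preserves the audiograms
  back <- read_cohort(f1)
  orig <- generate_cohort(cfg)
  expect_equal(as.matrix(back[, grep("^ac_", names(back))]),
               as.matrix(orig[, grep("^ac_", names(orig))]),
               ignore_attr = TRUE)
  unlink(c(f1, f2))
})

test_that("recovery labels are emergent: re-scoring audiograms reproduces them", {
  coh <- small_cohort()
  stripped <- coh
  stripped$recovered_ppsc <- NULL
  stripped$class_ppsc <- NULL
  sc <- score_cohort(stripped, "ppsc")
  expect_equal(as.logical(coh$recovered_ppsc), sc$recovered)
  expect_equal(coh$class_ppsc, sc$class)
})

test_that("initial audiogram sampler honours shape, run and feasibility", {
  set.seed(2)
  for (shape in audiogram_shapes()) {
    lo <- if (shape == "deaf") 95 else if (shape == "u_shaped") 40 else 35
    hi <- if (shape == "deaf") 110 else 80
    for (i in 1:200) {
      a <- sample_initial_audiogram(shape, runif(1, lo, hi))
      expect_equal(classify_audiogram_shape(a), shape)
      expect_false(is.null(detect_impaired_range(a)))
      expect_true(all(a == 5 * round(a / 5)))
    }
  }
  expect_error(sample_initial_audiogram("deaf", 35), "infeasible")
  expect_error(sample_initial_audiogram("flat", 95), "infeasible")
  expect_error(sample_initial_audiogram("flat", 20), "infeasible")
})

test_that("deaf audiograms are impaired across the whole grid", {
  set.seed(3)
  for (i in 1:20) {
    a <- sample_initial_audiogram("deaf", runif(1, 95, 110))
    r <- detect_impaired_range(a)
    expect_equal(r$length, 8)
  }
})

test_that("post-treatment sampler respects floors, caps and the prognosis direction", {
  set.seed(4)
  gains_hi <- gains_lo <- numeric(0)
  for (i in 1:60) {
    a0 <- sample_initial_audiogram("flat", runif(1, 45, 75))
    hi <- sample_posttreatment_audiogram(a0, 0.95)
    lo <- sample_posttreatment_audiogram(a0, 0.05)
    expect_true(all(hi >= -10) && all(lo >= -10))
    expect_true(all(hi <= a0 + 5) && all(lo <= a0 + 5))
    r <- detect_impaired_range(a0)
    idx <- r$start:(r$start + r$length - 1)
    gains_hi <- c(gains_hi, mean(a0[idx]) - mean(hi[idx]))
    gains_lo <- c(gains_lo, mean(a0[idx]) - mean(lo[idx]))
  }
  expect_gt(mean(gains_hi), mean(gains_lo))  # higher prognosis, larger gain
})

test_that("zero-gain configuration grades every patient none", {
  coh <- generate_cohort(generator_config(n_patients = 50, seed = 17,
                                          zero_gain = TRUE))
  expect_true(all(coh$class_ppsc == "none"))
  expect_true(all(coh$recovered_ppsc == 0))
})

test_that("generated recovery rate matches the calibration target", {
  coh <- generate_cohort(generator_config(n_patients = 5000, seed = 71))
  rate <- mean(coh$recovered_ppsc)
  expect_lt(abs(rate - 0.379), 0.02)
  # stratum age medians track the calibrated values
  rec <- coh$recovered_ppsc == 1
  expect_lt(abs(median(coh$age[!rec]) - 55), 2)
  expect_lt(abs(median(coh$age[rec]) - 48), 2)
  # shape mix per stratum within Monte-Carlo reach of the calibrated mix
  deaf_nr <- mean(coh$shape_deaf[!rec])
  expect_lt(abs(deaf_nr - 0.302), 0.03)
})

test_that("missingness injection is MCAR at the configured rates and respects protection", {
  coh <- small_cohort()
  expect_true(all(!is.na(coh$pta_avg_affected)))
  expect_true(all(!is.na(coh$run_length)))
  expect_true(all(!is.na(coh$recovered_ppsc)))
  big <- generate_cohort(generator_config(n_patients = 5810, seed = 99))
  frac <- mean(is.na(big$triacylglycerol))
  # binomial 99% band around 0.401 at n = 5810
  expect_lt(abs(frac - 0.401), 2.58 * sqrt(0.401 * 0.599 / 5810) + 1e-9)
  # zero rate masks nothing
  same <- inject_missingness(coh, c(bun = 0))
  expect_identical(same$bun, coh$bun)
  expect_error(inject_missingness(coh, c(bun = 1.2)), "\\[0, 1\\]")
})

test_that("unaffected ear is stochastically better than the affected ear", {
  coh <- small_cohort()
  expect_gt(mean(coh$pta_avg_affected - coh$pta_avg_unaffected), 20)
  expect_gt(mean(coh$pta_avg_affected > coh$pta_avg_unaffected), 0.95)
})
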