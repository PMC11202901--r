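test_that("impaired-run detection matches the exhaustive oracle on all 2^8 patterns", {
  for (params in list(c(30, 3), c(30, 2), c(40, 3), c(25, 4))) {
    cfg <- detection_config(cutoff_db = params[1], min_run_length = params[2])
    for (bits in 0:255) {
      qual <- as.logical(bitwAnd(bits, 2^(0:7)) > 0)
      thr <- ifelse(qual, params[1] + 10, params[1] - 10)
      got <- detect_impaired_range(thr, cfg)
      want <- oracle_best_run(qual, params[2])
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(got$start, want$start)
        expect_equal(got$length, want$length)
      }
    }
  }
})

test_that("isolated high-frequency impairment is excluded from the selected run", {
  p <- fixture_contradiction_patient()
  r <- detect_impaired_range(p$aff_t0)
  expect_equal(r$freqs, c(0.125, 0.25, 0.5, 1))
  expect_equal(r$length, 4)
  # 8 kHz qualifies (40 dB) but sits outside the contiguous run
  expect_false(8 %in% r$freqs)
})

test_that("detection treats missing thresholds as non-qualifying and validates input", {
  thr <- c(70, NA, 65, 50, 45, 25, 25, 25)
  r <- detect_impaired_range(thr)
  expect_equal(r$start, 3)  # the NA at 0.25 kHz breaks the low run
  expect_equal(r$length, 3)
  expect_null(detect_impaired_range(rep(10, 8)))
  expect_error(detect_impaired_range(rep(50, 7)), "length")
  expect_error(detect_impaired_range(c(rep(50, 7), 150)), "\\[-10, 120\\]")
})

test_that("mean_pta is exact arithmetic and refuses missing data in range", {
  thr <- c(60, 65, 70, 60, 10, 10, 10, 10)
  r <- detect_impaired_range(thr)
  expect_equal(mean_pta(thr, r), 63.75)
  expect_equal(mean_pta(rep(42, 8), freqs = traditional_band()), 42)
  # re-summation oracle + translation equivariance on random audiograms
  set.seed(11)
  for (i in 1:25) {
    x <- runif(8, -10, 110)
    fr <- sample(freq_grid(), sample(2:8, 1))
    idx <- match(fr, freq_grid())
    expect_equal(mean_pta(x, freqs = fr), sum(x[idx]) / length(idx),
                 tolerance = 1e-12)
    expect_equal(mean_pta(x + 7, freqs = fr), mean_pta(x, freqs = fr) + 7,
                 tolerance = 1e-12)
  }
  thr[2] <- NA
  expect_error(mean_pta(thr, r), "missing threshold")
})

test_that("severity bands are a total monotone step function with half-open edges", {
  expect_equal(as.integer(severity_category(c(0, 39.99, 40, 60, 75.63, 80, 99.9, 100, 118))),
               c(1, 1, 2, 3, 3, 4, 4, 5, 5))
  grid <- seq(-10, 120, by = 0.25)
  lev <- as.integer(severity_category(grid))
  expect_true(all(lev %in% 1:5))
  expect_true(all(diff(lev) >= 0))
  expect_error(severity_category(NA_real_), "finite")
  expect_error(severity_category(Inf), "finite")
})

test_that("audiogram shape rules fire as specified on constructed profiles", {
  expect_equal(classify_audiogram_shape(rep(100, 8)), "deaf")
  expect_equal(classify_audiogram_shape(rep(95, 8)), "deaf")
  expect_equal(classify_audiogram_shape(c(70, 70, 65, 50, 45, 40, 35, 30)), "ascending")
  expect_equal(classify_audiogram_shape(c(30, 35, 40, 45, 50, 65, 70, 70)), "descending")
  expect_equal(classify_audiogram_shape(c(40, 40, 45, 60, 60, 45, 40, 40)), "u_shaped")
  expect_equal(classify_audiogram_shape(rep(45, 8)), "flat")
  expect_equal(classify_audiogram_shape(c(45, 45, 50, 45, 50, 45, 50, 45)), "flat")
  expect_error(classify_audiogram_shape(c(NA, rep(50, 7))), "missing")
})

test_that("derived features use one and the same range for both ears", {
  set.seed(21)
  for (i in 1:20) {
    shape <- sample(c("ascending", "descending", "flat", "u_shaped"), 1)
    tgt <- runif(1, 45, 75)
    aff <- sample_initial_audiogram(shape, tgt)
    una <- pmin(pmax(5 * round(runif(8, 0, 8)), -10), 120)
    f <- derive_audiometric_features(aff, una)
    idx <- f$range$start:(f$range$start + f$range$length - 1)
    expect_equal(f$pta_avg_affected, mean(aff[idx]))
    expect_equal(f$pta_avg_unaffected, mean(una[idx]))
    expect_equal(f$run_length, length(idx))
    expect_equal(sum(unlist(f[paste0("shape_", audiogram_shapes())])), 1)
    expect_equal(f$shape, shape)
  }
  expect_error(derive_audiometric_features(rep(10, 8), rep(10, 8)),
               "no qualifying")
})
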