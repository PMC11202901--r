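test_that("exclusion cascade removes each planted violation at its own rule", {
  plants <- c(duplicate_record = 2, missing_month1_pta = 5,
              missing_initial_pta = 3, bilateral = 4, no_qualifying_run = 3)
  coh <- generate_cohort(generator_config(n_patients = 60, seed = 9,
                                          plant_violations = plants))
  res <- apply_exclusion_cascade(coh)
  expect_equal(res$report$initial_n, 60 + sum(plants))
  expect_equal(res$report$excluded, plants)
  expect_equal(res$report$final_n, 60)
  expect_equal(res$report$final_n,
               res$report$initial_n - sum(res$report$excluded))
  expect_true(all(res$cohort$plant == "none"))
})

test_that("a clean cohort passes the cascade untouched", {
  coh <- small_cohort()
  res <- apply_exclusion_cascade(coh)
  expect_equal(res$report$final_n, nrow(coh))
  expect_true(all(res$report$excluded == 0))
})

test_that("rule order changes per-step counts but never final membership", {
  # a patient violating several rules is always removed exactly once
  plants <- c(missing_month1_pta = 4, bilateral = 4)
  coh <- generate_cohort(generator_config(n_patients = 40, seed = 31,
                                          plant_violations = plants))
  # make two bilateral plants ALSO miss month-1 audiometry
  bil <- which(coh$plant == "bilateral")[1:2]
  coh[bil, grep("^ac_aff_.*_t1$", names(coh))[1]] <- NA
  res <- apply_exclusion_cascade(coh)
  # those two are now caught by the earlier missing-month1 rule
  expect_equal(unname(res$report$excluded["missing_month1_pta"]), 6)
  expect_equal(unname(res$report$excluded["bilateral"]), 2)
  expect_equal(res$report$final_n, 40)
})

test_that("assessment shift counts match a direct pairwise oracle", {
  set.seed(5)
  for (i in 1:10) {
    n <- 80
    ids <- sprintf("P%03d", 1:n)
    rt <- runif(n) < 0.45
    rp <- runif(n) < 0.4
    tr <- data.frame(patient_id = ids, recovered = rt)
    pp <- data.frame(patient_id = sample(ids), stringsAsFactors = FALSE)
    pp$recovered <- rp[match(pp$patient_id, ids)]
    sh <- assessment_shift(tr, pp)
    expect_equal(sh$n_up, sum(!rt & rp))
    expect_equal(sh$n_down, sum(rt & !rp))
    expect_equal(sh$n_changed, sh$n_up + sh$n_down)
    expect_equal(unname(rowSums(sh$table)), c(n, n))
    expect_equal(unname(sh$table["ppsc", "recovered"]),
                 unname(sh$table["traditional", "recovered"]) - sh$n_down + sh$n_up)
  }
  expect_error(assessment_shift(data.frame(patient_id = "a", recovered = TRUE),
                                data.frame(patient_id = "b", recovered = TRUE)),
               "same patients")
})

test_that("identical score sets produce a zero shift", {
  tr <- data.frame(patient_id = sprintf("P%02d", 1:20),
                   recovered = rep(c(TRUE, FALSE), 10))
  sh <- assessment_shift(tr, tr)
  expect_equal(sh$n_changed, 0)
  expect_equal(sh$table[1, ], sh$table[2, ])
})

test_that("2x2 chi-square equals the textbook formula, uncorrected", {
  set.seed(8)
  for (i in 1:12) {
    tab <- matrix(sample(5:80, 4), 2)
    got <- suppressWarnings(chi_square_2x2(tab))  # small-count approximation note
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(got$statistic, sum((tab - E)^2 / E), tolerance = 1e-9)
    expect_equal(got$p_value, pchisq(got$statistic, 1, lower.tail = FALSE))
  }
  expect_equal(chi_square_2x2(rbind(c(10, 20), c(10, 20)))$statistic, 0)
  expect_equal(chi_square_2x2(rbind(c(10, 20), c(10, 20)))$p_value, 1)
  expect_error(chi_square_2x2(rbind(c(0, 0), c(5, 5))), "marginal")
})

test_that("McNemar view of the shift uses only discordant patients", {
  tr <- data.frame(patient_id = sprintf("P%03d", 1:100),
                   recovered = c(rep(TRUE, 50), rep(FALSE, 50)))
  pp <- tr
  pp$recovered[1:10] <- FALSE   # 10 down
  pp$recovered[51:53] <- TRUE   # 3 up
  m <- mcnemar_shift(assessment_shift(tr, pp), correct = FALSE)
  expect_equal(m$statistic, (10 - 3)^2 / 13)
})

test_that("group comparison detects planted shifts and skips constants", {
  set.seed(77)
  n <- 240
  coh <- data.frame(recovered_ppsc = rep(c(0, 1), each = n / 2))
  coh$age <- round(rnorm(n, mean = ifelse(coh$recovered_ppsc == 1, 45, 60), sd = 6))
  coh$height <- rnorm(n, 165, 7)               # no group difference
  coh$dizziness <- rbinom(n, 1, ifelse(coh$recovered_ppsc == 1, 0.15, 0.45))
  coh$ckd <- 0                                  # constant
  out <- compare_groups(coh, vars = c("age", "height", "dizziness", "ckd"))
  expect_equal(nrow(out), 4)
  expect_lt(out$p_value[out$variable == "age"], 0.001)
  expect_gt(out$p_value[out$variable == "height"], 0.05)
  expect_lt(out$p_value[out$variable == "dizziness"], 0.001)
  expect_true(grepl("skipped", out$test[out$variable == "ckd"]))
  expect_true(is.na(out$p_value[out$variable == "ckd"]))
})

test_that("calibrated generator reproduces the direction of key group contrasts", {
  coh <- generate_cohort(generator_config(n_patients = 1200, seed = 55))
  rec <- coh$recovered_ppsc == 1
  expect_gt(median(coh$age[!rec]), median(coh$age[rec]))
  expect_gt(mean(coh$dizziness[!rec], na.rm = TRUE),
            mean(coh$dizziness[rec], na.rm = TRUE))
  expect_lt(mean(coh$tinnitus[!rec], na.rm = TRUE),
            mean(coh$tinnitus[rec], na.rm = TRUE))
  expect_gt(median(coh$pta_avg_affected[!rec]), median(coh$pta_avg_affected[rec]))
  expect_gt(mean(coh$shape_deaf[!rec]), mean(coh$shape_deaf[rec]))
})
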