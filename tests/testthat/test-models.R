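test_that("confusion metrics reproduce the reference soft-voting column", {
  m <- confusion_metrics(list(tp = 33, fp = 15, fn = 11, tn = 58))
  expect_equal(round(unname(m["recall"]), 3), 0.750)
  expect_equal(round(unname(m["precision"]), 3), 0.688)
  expect_equal(round(unname(m["balanced_accuracy"]), 3), 0.772)
  expect_equal(round(unname(m["f1"]), 3), 0.717)
})

test_that("confusion metrics match the formulas and flag empty denominators", {
  expect_equal(unname(confusion_metrics(list(tp = 10, fp = 0, fn = 0, tn = 10))),
               c(1, 1, 1, 1))
  set.seed(6)
  for (i in 1:20) {
    cm <- as.list(setNames(sample(1:50, 4), c("tp", "fp", "fn", "tn")))
    m <- confusion_metrics(cm)
    expect_equal(unname(m["recall"]), cm$tp / (cm$tp + cm$fn))
    expect_equal(unname(m["precision"]), cm$tp / (cm$tp + cm$fp))
    expect_equal(unname(m["balanced_accuracy"]),
                 (cm$tp / (cm$tp + cm$fn) + cm$tn / (cm$tn + cm$fp)) / 2)
    expect_equal(unname(m["f1"]),
                 2 * cm$tp / (2 * cm$tp + cm$fp + cm$fn))
  }
  expect_true(is.na(confusion_metrics(list(tp = 0, fp = 0, fn = 5, tn = 5))["precision"]))
})

test_that("AUROC equals the exhaustive pairwise-concordance oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  set.seed(7)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    y <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    s <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # many ties
    expect_equal(auroc(s, y), oracle_auroc_pairs(s, y), tolerance = 1e-12)
  }
  expect_error(auroc(1:4, rep(TRUE, 4)), "both classes")
  # null limit
  set.seed(8)
  expect_lt(abs(auroc(runif(4000), runif(4000) < 0.5) - 0.5), 0.03)
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  s <- runif(60); y <- runif(60) < 0.4
  expect_equal(auroc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("ROC curve is monotone and integrates to the AUROC", {
  set.seed(10)
  s <- sample(seq(0, 1, 0.1), 50, replace = TRUE)
  y <- runif(50) < 0.5
  rc <- roc_curve(s, y)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
  trap <- sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
  expect_equal(trap, auroc(s, y), tolerance = 1e-12)
})

test_that("bootstrap AUROC interval is stratified and brackets the point", {
  set.seed(11)
  s <- c(rnorm(40, 1), rnorm(60)); y <- rep(c(TRUE, FALSE), c(40, 60))
  ci <- auroc_ci(s, y, n_boot = 300)
  expect_lte(ci$ci[1], ci$auroc)
  expect_gte(ci$ci[2], ci$auroc)
  expect_gt(ci$ci[1], 0.5)
})

test_that("soft voting is the unweighted mean with ties classified positive", {
  x <- matrix(0, 3, 2)
  mk <- function(p) structure(list(p = p), class = "const_model")
  registerS3method("predict_prob", "const_model",
                   function(model, x) rep(model$p, nrow(x)),
                   envir = asNamespace("ppsc"))
  models <- list(mk(0.7), mk(0.7), mk(0.7))
  expect_equal(soft_vote(models, x)$prob, rep(0.7, 3))
  half <- soft_vote(list(mk(0), mk(1), mk(0), mk(1)), x)
  expect_equal(half$prob, rep(0.5, 3))
  expect_true(all(half$label))  # 0.5 classified positive
  # permutation invariance and bounds, against a re-averaging oracle
  set.seed(12)
  ps <- runif(8)
  models <- lapply(ps, mk)
  v1 <- soft_vote(models, x)$prob
  v2 <- soft_vote(models[sample(8)], x)$prob
  expect_equal(v1, v2, tolerance = 1e-12)
  expect_equal(v1[1], mean(ps), tolerance = 1e-12)
  expect_true(all(v1 >= min(ps) & v1 <= max(ps)))
})

test_that("cost-complexity pruning shrinks the tree monotonically in alpha", {
  set.seed(13)
  n <- 400
  x <- matrix(runif(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
  y <- (x[, 1] > 0.5) != (x[, 2] > 0.6 & runif(n) < 0.8)
  leaves <- vapply(c(0, 0.005, 0.01, 0.02, 0.05, 0.1, 0.3), function(a) {
    m <- fit_model("decision_tree", x, y, list(ccp_alpha = a), seed = 1)
    ppsc:::n_leaves(m$fit)
  }, numeric(1))
  expect_true(all(diff(leaves) <= 0))
  expect_gt(leaves[1], leaves[length(leaves)])
  expect_equal(leaves[length(leaves)], 1)  # heavy penalty prunes to the root
})

test_that("every family fits, predicts probabilities, and separates easy data", {
  set.seed(14)
  n <- 160
  x <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("f", 1:4)))
  y <- x[, 1] + 0.5 * x[, 2] + rnorm(n, 0, 0.4) > 0
  grids <- default_grids(FALSE)
  for (fam in model_families()) {
    m <- fit_model(fam, x, y, grids[[fam]][1, , drop = FALSE], seed = 2)
    p <- predict_prob(m, x)
    expect_length(p, n)
    expect_true(all(p >= 0 & p <= 1))
    expect_gt(auroc(p, y), 0.8)
  }
  # linearly separable data: the margin model ranks the classes perfectly
  ysep <- x[, 1] > 0
  msep <- fit_model("svm_linear", x, ysep,
                    data.frame(C = 100, kernel = "linear", degree = 2),
                    seed = 2)  # near-hard margin
  dv <- as.numeric(attr(predict(msep$fit, x, decision.values = TRUE),
                        "decision.values"))
  expect_equal(max(auroc(dv, ysep), 1 - auroc(dv, ysep)), 1)
  # the calibrated probabilities track the margin almost perfectly
  expect_gt(auroc(predict_prob(msep, x), ysep), 0.99)
})

test_that("grid search picks the single point of a one-point grid and tie-breaks first", {
  set.seed(15)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- x[, 1] > 0
  m <- tune_and_fit("logistic", x, y, data.frame(C = 0.7), seed = 3)
  expect_equal(attr(m, "best_params")$C, 0.7)
  # duplicated rows give identical scores; the first must win
  g2 <- data.frame(C = c(1.0, 1.0))
  m2 <- tune_and_fit("logistic", x, y, g2, seed = 3)
  expect_equal(rownames(attr(m2, "best_params")), "1")
})

test_that("label-permuted data yields chance-level tuned validation AUROC", {
  set.seed(16)
  n <- 500
  x <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("f", 1:6)))
  y <- sample(rep(c(TRUE, FALSE), c(200, 300)))
  plan <- make_split_plan(y, seed = 5, n_repeats = 1, n_folds = 5)
  val <- run_validation(x, y, plan, default_grids(FALSE))
  expect_true(all(val$summary$auroc > 0.35 & val$summary$auroc < 0.65))
  expect_equal(nrow(val$summary), 9)  # 8 families + the ensemble
})
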