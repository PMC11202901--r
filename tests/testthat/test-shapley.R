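# a deterministic linear "model" exercised through the generic surface
linear_predict <- function(model, x) drop(as.matrix(x) %*% model$beta)

test_that("attributions satisfy local accuracy exactly per patient", {
  set.seed(20)
  X <- matrix(rnorm(15 * 5), 15, dimnames = list(NULL, paste0("f", 1:5)))
  bg <- matrix(rnorm(30 * 5), 30, dimnames = list(NULL, paste0("f", 1:5)))
  mod <- list(beta = c(1.5, -2, 0.3, 0, 0.8))
  s <- shapley_attributions(mod, X, bg, n_perm = 25, seed = 2,
                            predict_fun = linear_predict)
  expect_equal(rowSums(s$values), s$pred - s$base, tolerance = 1e-10)
})

test_that("an ignored feature receives zero attribution", {
  set.seed(21)
  X <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, paste0("f", 1:5)))
  bg <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, paste0("f", 1:5)))
  mod <- list(beta = c(2, -1, 1, 0, 0.5))
  s <- shapley_attributions(mod, X, bg, n_perm = 30, seed = 3,
                            predict_fun = linear_predict)
  expect_equal(unname(s$mean_abs["f4"]), 0)
  expect_gt(unname(s$mean_abs["f1"]), 0)
})

test_that("linear models recover coefficient x deviation within Monte-Carlo error", {
  set.seed(22)
  p <- 4
  X <- matrix(rnorm(30 * p), 30, dimnames = list(NULL, paste0("f", 1:p)))
  bg <- matrix(rnorm(80 * p), 80, dimnames = list(NULL, paste0("f", 1:p)))
  beta <- c(2, -1, 0.5, 0)
  s <- shapley_attributions(list(beta = beta), X, bg, n_perm = 400, seed = 4,
                            predict_fun = linear_predict)
  expected <- sweep(X, 2, colMeans(bg)) %*% diag(beta)
  expect_lt(mean(abs(s$values - expected)), 0.12)
  expect_lt(max(abs(s$values - expected)), 0.6)
})

test_that("duplicated identical features share attribution symmetrically", {
  set.seed(23)
  n <- 20
  base_col <- rnorm(n)
  X <- cbind(a = base_col, b = base_col, c = rnorm(n))
  bgcol <- rnorm(50)
  bg <- cbind(a = bgcol, b = bgcol, c = rnorm(50))
  mod <- list(beta = c(1, 1, 0.5))
  s <- shapley_attributions(mod, X, bg, n_perm = 600, seed = 5,
                            predict_fun = linear_predict)
  expect_lt(abs(s$mean_abs["a"] - s$mean_abs["b"]) / s$mean_abs["a"], 0.1)
})

test_that("attribution is deterministic under a fixed seed and background", {
  set.seed(24)
  X <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, paste0("f", 1:5)))
  bg <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, paste0("f", 1:5)))
  mod <- list(beta = rnorm(5))
  s1 <- shapley_attributions(mod, X, bg, n_perm = 10, seed = 9,
                             predict_fun = linear_predict)
  s2 <- shapley_attributions(mod, X, bg, n_perm = 10, seed = 9,
                             predict_fun = linear_predict)
  expect_identical(s1$values, s2$values)
  expect_error(shapley_attributions(mod, X, bg[0, ], predict_fun = linear_predict),
               "empty")
})

test_that("ranking equals a re-sort of the column mean absolute values", {
  set.seed(25)
  X <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, paste0("f", 1:5)))
  bg <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, paste0("f", 1:5)))
  mod <- list(beta = c(0.1, 3, -2, 0.5, 1))
  s <- shapley_attributions(mod, X, bg, n_perm = 50, seed = 6,
                            predict_fun = linear_predict)
  expect_equal(s$ranking, names(sort(colMeans(abs(s$values)), decreasing = TRUE)))
  full <- rank_attributions(s, X, k = 5)
  expect_equal(full$table$feature, s$ranking)
  one <- rank_attributions(s, X, k = 1)
  expect_equal(nrow(one$table), 1)
  expect_equal(one$table$feature, s$ranking[1])
  # k larger than the feature count is capped
  expect_equal(nrow(rank_attributions(s, X, k = 50)$table), 5)
})

test_that("planted severity effect attributes negatively for high thresholds", {
  coh <- generate_cohort(generator_config(n_patients = 300, seed = 61))
  fm <- build_feature_matrix(coh)
  plan <- make_split_plan(fm$y, seed = 7, n_repeats = 1, n_folds = 2)
  prep <- ppsc:::preprocess_fit(fm$x[plan$train_idx, ])
  xte <- ppsc:::preprocess_apply(prep, fm$x[plan$test_idx, ])
  m <- fit_model("logistic", prep$train, fm$y[plan$train_idx],
                 data.frame(C = 1), seed = 8)
  s <- shapley_attributions(m, xte, prep$train[1:60, ], n_perm = 20, seed = 9)
  r <- rank_attributions(s, xte, k = 20)
  row <- r$table[r$table$feature == "pta_avg_affected", ]
  expect_equal(nrow(row), 1)          # among the top features
  expect_lt(row$direction, 0)         # higher threshold -> lower recovery prob
})
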