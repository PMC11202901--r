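# The candidate classifier zoo: eight model families with the published
# tuning grids, inner-cross-validation grid search, and the soft-voting
# ensemble. Every family exposes the same surface: fit on a numeric
# matrix + binary labels, predict a positive-class probability.
#
# Class weighting (inverse class frequency) applies to the logistic,
# decision-tree, random-forest, linear-SVM and leaf-wise-boosting
# families; AdaBoost and the level-wise gradient-boosting family run
# unweighted.

MODEL_FAMILY_NAMES <- c("logistic", "decision_tree", "random_forest",
                        "svm_linear", "adaboost", "xgb", "lgbm", "knn")

#' Model family names
#' @return Character vector of the eight candidate families.
#' @export
model_families <- function() MODEL_FAMILY_NAMES

#' Hyperparameter grids for the model zoo
#'
#' The grid-search value sets for each family. With `full = TRUE` the
#' complete search grids; with `full = FALSE` the single best parameter
#' set found by the full search (useful when the surrounding protocol,
#' not the search itself, is under study -- the repeated-validation and
#' pipeline runs in this package default to the compact grids for
#' tractable run times; see the methods vignette).
#'
#' @param full Return the full search grids (`TRUE`) or the single-point
#'   optima (`FALSE`).
#' @return Named list of data.frames, one grid row per candidate setting.
#' @export
default_grids <- function(full = TRUE) {
  if (full) {
    list(
      logistic = expand.grid(C = c(0.7, 1.0, 1.2)),
      decision_tree = expand.grid(ccp_alpha = c(0.005, 0.01, 0.015, 0.02, 0.025)),
      random_forest = expand.grid(n_estimators = c(50, 100, 150),
                                  ccp_alpha = c(0.01, 0.05, 0.1)),
      svm_linear = expand.grid(C = c(0.4, 0.6, 0.8), kernel = "linear",
                               degree = c(2, 3), stringsAsFactors = FALSE),
      adaboost = expand.grid(n_estimators = c(20, 40, 60, 100),
                             learning_rate = c(0.6, 1.0, 1.4)),
      xgb = expand.grid(n_estimators = c(50, 100, 200),
                        learning_rate = c(0.6, 0.8, 1.0, 1.2),
                        reg_alpha = c(0.4, 0.8, 1.2, 1.6),
                        reg_lambda = c(1.4, 1.8, 2.2, 2.6),
                        gamma = c(0.6, 1.0, 1.4, 1.8)),
      lgbm = expand.grid(n_estimators = c(25, 50, 100),
                         learning_rate = c(0.2, 0.4, 0.6, 0.8, 1.0),
                         reg_alpha = c(0.8, 1.2, 1.6, 2.0),
                         reg_lambda = c(0.8, 1.2, 1.6, 2.0)),
      knn = expand.grid(n_neighbors = c(5, 10, 15, 20, 25),
                        weights = c("uniform", "distance"),
                        stringsAsFactors = FALSE)
    )
  } else {
    list(
      logistic = data.frame(C = 1.0),
      decision_tree = data.frame(ccp_alpha = 0.02),
      random_forest = data.frame(n_estimators = 100, ccp_alpha = 0.05),
      svm_linear = data.frame(C = 0.6, kernel = "linear", degree = 2,
                              stringsAsFactors = FALSE),
      adaboost = data.frame(n_estimators = 20, learning_rate = 0.6),
      xgb = data.frame(n_estimators = 50, learning_rate = 0.6,
                       reg_alpha = 0.8, reg_lambda = 2.6, gamma = 0.6),
      lgbm = data.frame(n_estimators = 25, learning_rate = 0.2,
                        reg_alpha = 2.0, reg_lambda = 2.0),
      knn = data.frame(n_neighbors = 25, weights = "distance",
                       stringsAsFactors = FALSE)
    )
  }
}

# inverse-class-frequency case weights, mean 1
balanced_weights <- function(y) {
  n <- length(y)
  w <- n / (2 * ifelse(y, sum(y), sum(!y)))
  w
}

#' Fit one model family with fixed hyperparameters
#'
#' @param family One of [model_families()].
#' @param x Numeric training matrix (preprocessed).
#' @param y Logical/0-1 labels (positive = recovered).
#' @param params One-row data.frame (or list) of hyperparameters in the
#'   family's grid schema; see [default_grids()].
#' @param seed Integer seed for the stochastic families.
#' @return A fitted model of class `ppsc_model`; predict positive-class
#'   probabilities with [predict_prob()].
#' @export
fit_model <- function(family, x, y, params, seed = 1) {
  family <- match.arg(family, MODEL_FAMILY_NAMES)
  x <- as.matrix(x); y <- as.logical(y)
  params <- as.list(params)
  fitter <- switch(family,
                   logistic = fit_logistic, decision_tree = fit_tree,
                   random_forest = fit_forest, svm_linear = fit_svm,
                   adaboost = fit_adaboost, xgb = fit_xgb,
                   lgbm = fit_lgbm, knn = fit_knn)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  fit <- fitter(x, y, params)
  structure(list(family = family, params = params, fit = fit,
                 features = colnames(x)),
            class = "ppsc_model")
}

#' Predict positive-class probabilities
#'
#' @param model A `ppsc_model` from [fit_model()] or an ensemble from
#'   [soft_vote_fit()].
#' @param x Numeric matrix with the training columns.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(model, x) UseMethod("predict_prob")

#' @export
predict_prob.ppsc_model <- function(model, x) {
  x <- as.matrix(x)
  if (!is.null(model$features)) x <- x[, model$features, drop = FALSE]
  predictor <- switch(model$family,
                      logistic = pred_logistic, decision_tree = pred_tree,
                      random_forest = pred_forest, svm_linear = pred_svm,
                      adaboost = pred_adaboost, xgb = pred_xgb,
                      lgbm = pred_xgb, knn = pred_knn)
  p <- predictor(model$fit, x)
  pmin(pmax(as.numeric(p), 0), 1)
}

#' @export
print.ppsc_model <- function(x, ...) {
  cat("<ppsc_model>", x$family, "|",
      paste(names(x$params), unlist(lapply(x$params, format)),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

## -- family implementations ------------------------------------------------

# L2-regularised logistic regression; penalty strength C on the usual
# inverse scale (lambda = 1 / (C * n)), class-balanced case weights.
fit_logistic <- function(x, y, params) {
  w <- balanced_weights(y)
  glmnet::glmnet(x, factor(y), family = "binomial", alpha = 0,
                 lambda = 1 / (params$C * nrow(x)), weights = w,
                 standardize = FALSE)
}
pred_logistic <- function(fit, x) {
  as.numeric(stats::predict(fit, x, type = "response"))
}

# cost-complexity-pruned classification tree. The pruning parameter is the
# absolute per-observation complexity penalty alpha; rpart's cp is relative
# to the root risk, so alpha is rescaled before pruning.
fit_tree <- function(x, y, params) {
  df <- data.frame(y = factor(y, levels = c(FALSE, TRUE)), x, check.names = FALSE)
  w <- balanced_weights(y)
  fit <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                      control = rpart::rpart.control(cp = 0, xval = 0,
                                                     minsplit = 10))
  prune_ccp(fit, params$ccp_alpha)
}
# root risk per observation, on rpart's weighted scale
rpart_root_risk <- function(fit) {
  fit$frame$dev[1] / fit$frame$wt[1]
}
prune_ccp <- function(fit, alpha) {
  rel_cp <- alpha / max(rpart_root_risk(fit), .Machine$double.eps)
  rpart::prune(fit, cp = rel_cp)
}
pred_tree <- function(fit, x) {
  stats::predict(fit, data.frame(x, check.names = FALSE), type = "prob")[, "TRUE"]
}

# bootstrap forest of cost-complexity-pruned trees with random feature
# subspaces; probability = mean of the tree class probabilities
fit_forest <- function(x, y, params) {
  n <- nrow(x); p <- ncol(x)
  mtry <- max(1L, floor(sqrt(p)))
  trees <- vector("list", params$n_estimators)
  w <- balanced_weights(y)
  for (b in seq_len(params$n_estimators)) {
    rows <- sample(n, n, replace = TRUE)
    feats <- sort(sample(p, min(p, max(mtry * 3, 8))))
    df <- data.frame(y = factor(y[rows], levels = c(FALSE, TRUE)),
                     x[rows, feats, drop = FALSE], check.names = FALSE)
    fit <- rpart::rpart(y ~ ., data = df, weights = w[rows], method = "class",
                        control = rpart::rpart.control(cp = 0, xval = 0,
                                                       minsplit = 5))
    trees[[b]] <- list(tree = prune_ccp(fit, params$ccp_alpha),
                       features = colnames(x)[feats])
  }
  trees
}
pred_forest <- function(fit, x) {
  probs <- vapply(fit, function(t) {
    stats::predict(t$tree,
                   data.frame(x[, t$features, drop = FALSE], check.names = FALSE),
                   type = "prob")[, "TRUE"]
  }, numeric(nrow(x)))
  if (nrow(x) == 1) mean(probs) else rowMeans(probs)
}

# soft-margin linear SVM; probabilities by Platt-style sigmoid calibration
# (the probability model fitted within e1071's internal cross-validation)
fit_svm <- function(x, y, params) {
  cw <- c("FALSE" = length(y) / (2 * sum(!y)), "TRUE" = length(y) / (2 * sum(y)))
  e1071::svm(x, factor(y, levels = c(FALSE, TRUE)), kernel = "linear",
             cost = params$C, probability = TRUE, class.weights = cw,
             scale = FALSE)
}
pred_svm <- function(fit, x) {
  attr(stats::predict(fit, x, probability = TRUE), "probabilities")[, "TRUE"]
}

# discrete AdaBoost with depth-1 stumps; probability via the logistic of
# the normalised ensemble margin
fit_adaboost <- function(x, y, params) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  yy <- ifelse(y, 1, -1)
  stumps <- list()
  alphas <- numeric(0)
  df <- data.frame(x, check.names = FALSE)
  for (m in seq_len(params$n_estimators)) {
    dfm <- data.frame(y = factor(y, levels = c(FALSE, TRUE)), df,
                      check.names = FALSE)
    stump <- rpart::rpart(y ~ ., data = dfm, weights = w * n, method = "class",
                          control = rpart::rpart.control(maxdepth = 1, cp = 0,
                                                         xval = 0, minsplit = 2))
    pred <- ifelse(stats::predict(stump, df, type = "class") == "TRUE", 1, -1)
    err <- sum(w * (pred != yy))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    if (err >= 0.5 && m > 1) break
    alpha <- params$learning_rate * 0.5 * log((1 - err) / err)
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    stumps[[length(stumps) + 1L]] <- stump
    alphas <- c(alphas, alpha)
  }
  list(stumps = stumps, alphas = alphas)
}
pred_adaboost <- function(fit, x) {
  df <- data.frame(x, check.names = FALSE)
  score <- rep(0, nrow(x))
  for (m in seq_along(fit$stumps)) {
    pred <- ifelse(stats::predict(fit$stumps[[m]], df, type = "class") == "TRUE",
                   1, -1)
    score <- score + fit$alphas[m] * pred
  }
  denom <- sum(abs(fit$alphas))
  if (denom == 0) return(rep(0.5, nrow(x)))
  1 / (1 + exp(-2 * score / denom))
}

# level-wise gradient-boosted trees
fit_xgb <- function(x, y, params) {
  d <- xgboost::xgb.DMatrix(x, label = as.numeric(y))
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 6,
                  eta = params$learning_rate, alpha = params$reg_alpha,
                  lambda = params$reg_lambda, gamma = params$gamma,
                  nthread = 1),
    data = d, nrounds = params$n_estimators, verbose = 0)
}
# leaf-wise gradient-boosted trees (histogram split finding, loss-guided
# growth capped at 31 leaves), class-balanced via scale_pos_weight
fit_lgbm <- function(x, y, params) {
  d <- xgboost::xgb.DMatrix(x, label = as.numeric(y))
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", tree_method = "hist",
                  grow_policy = "lossguide", max_depth = 0, max_leaves = 31,
                  eta = params$learning_rate, alpha = params$reg_alpha,
                  lambda = params$reg_lambda,
                  scale_pos_weight = sum(!y) / max(sum(y), 1),
                  nthread = 1),
    data = d, nrounds = params$n_estimators, verbose = 0)
}
pred_xgb <- function(fit, x) {
  stats::predict(fit, xgboost::xgb.DMatrix(x))
}

# k-nearest-neighbour classification with uniform or inverse-distance vote
fit_knn <- function(x, y, params) {
  list(x = x, y = y, k = params$n_neighbors, weights = params$weights)
}
pred_knn <- function(fit, x) {
  k <- min(fit$k, nrow(fit$x))
  d2 <- outer(rowSums(x^2), rep(1, nrow(fit$x))) +
    outer(rep(1, nrow(x)), rowSums(fit$x^2)) - 2 * x %*% t(fit$x)
  d2 <- pmax(d2, 0)
  vapply(seq_len(nrow(x)), function(i) {
    nn <- order(d2[i, ])[seq_len(k)]
    if (fit$weights == "distance") {
      w <- 1 / pmax(sqrt(d2[i, nn]), 1e-12)
    } else {
      w <- rep(1, k)
    }
    sum(w[fit$y[nn]]) / sum(w)
  }, numeric(1))
}

## -- grid search and ensemble ----------------------------------------------

#' Grid-search tuning with inner stratified cross-validation
#'
#' Exhaustively evaluates every row of the family's hyperparameter grid by
#' mean AUROC over `tune_folds` stratified folds of the training rows,
#' then refits on all training rows with the best setting. Ties are broken
#' towards the earlier grid row.
#'
#' @inheritParams fit_model
#' @param grid Data.frame of candidate settings (one per row); see
#'   [default_grids()].
#' @param tune_folds Number of inner folds (default 3).
#' @param seed Integer seed for fold assignment and stochastic fits.
#' @return A `ppsc_model` with attributes `best_params` and `tuning`
#'   (per-candidate mean AUROC).
#' @export
tune_and_fit <- function(family, x, y, grid, tune_folds = 3, seed = 1) {
  x <- as.matrix(x); y <- as.logical(y)
  if (nrow(grid) == 1) {
    best <- 1L
    scores <- NA_real_
  } else {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    fold <- stratified_folds(y, tune_folds)
    scores <- vapply(seq_len(nrow(grid)), function(g) {
      aucs <- vapply(seq_len(tune_folds), function(f) {
        tr <- fold != f
        m <- fit_model(family, x[tr, , drop = FALSE], y[tr],
                       grid[g, , drop = FALSE], seed = seed + f)
        auroc(predict_prob(m, x[!tr, , drop = FALSE]), y[!tr])
      }, numeric(1))
      mean(aucs)
    }, numeric(1))
    best <- which.max(scores)  # first maximum = earliest grid row
  }
  model <- fit_model(family, x, y, grid[best, , drop = FALSE], seed = seed)
  attr(model, "best_params") <- grid[best, , drop = FALSE]
  attr(model, "tuning") <- scores
  model
}

#' Fit the full model zoo
#'
#' Tunes and fits all eight families on the same training matrix.
#'
#' @inheritParams tune_and_fit
#' @param grids Named list of grids as returned by [default_grids()].
#' @return Named list of `ppsc_model` objects.
#' @export
fit_model_zoo <- function(x, y, grids = default_grids(FALSE),
                          tune_folds = 3, seed = 1) {
  models <- lapply(seq_along(MODEL_FAMILY_NAMES), function(i) {
    fam <- MODEL_FAMILY_NAMES[i]
    tune_and_fit(fam, x, y, grids[[fam]], tune_folds = tune_folds,
                 seed = seed + i)
  })
  names(models) <- MODEL_FAMILY_NAMES
  models
}

#' Soft-voting ensemble
#'
#' `soft_vote()` averages the positive-class probabilities of the fitted
#' component models with equal weights; the predicted label is positive
#' when the averaged probability is at least 0.5 (ties classified
#' positive). `soft_vote_fit()` wraps fitted components into a
#' `ppsc_ensemble` usable wherever a single model is.
#'
#' @param models Named list of fitted `ppsc_model` objects.
#' @param x Numeric matrix to predict.
#' @return `soft_vote()`: a list with `prob` and `label`.
#' @export
soft_vote <- function(models, x) {
  probs <- vapply(models, function(m) predict_prob(m, x), numeric(nrow(x)))
  p <- if (nrow(x) == 1) mean(probs) else rowMeans(probs)
  list(prob = p, label = p >= 0.5)
}

#' @rdname soft_vote
#' @export
soft_vote_fit <- function(models) {
  structure(list(models = models), class = "ppsc_ensemble")
}

#' @export
predict_prob.ppsc_ensemble <- function(model, x) {
  soft_vote(model$models, as.matrix(x))$prob
}

# leaf count of a pruned rpart tree (used by the pruning diagnostics)
n_leaves <- function(tree) sum(tree$frame$var == "<leaf>")
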