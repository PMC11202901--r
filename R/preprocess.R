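# Preprocessing: round-robin chained-equations imputation, integer
# rounding, min-max scaling, and the stratified split/fold machinery.
# Every state object is fitted on training rows only and applied, frozen,
# to held-out rows.

#' Fit and apply chained-equations imputation
#'
#' Round-robin regression imputation. Missing cells are initialised with
#' the per-feature training medians; then, cycling over the features with
#' missing values from fewest to most missing, each feature is regressed
#' on all others by a ridge-regularised linear model and its missing cells
#' are overwritten with the fitted predictions. Cycles repeat until the
#' largest change in any imputed cell (in units of the feature's standard
#' deviation) drops below `tol`, or `max_iter` cycles. Binary and integer
#' features are imputed on the linear scale; rounding is a separate,
#' later step ([round_integer_features()]).
#'
#' @param x Numeric matrix or data.frame (patients x features) with `NA`s.
#' @param max_iter Maximum number of round-robin cycles (default 20).
#' @param tol Convergence tolerance on scaled imputed-cell changes.
#' @param ridge Ridge penalty (relative; scaled by n internally).
#' @return A list with `data` (the completed matrix) and `state`, an
#'   `imputer_state` holding the feature order, the fitted regression
#'   coefficients, the training medians, the iteration count and the
#'   convergence flag. Apply to new data with [apply_imputer()].
#' @export
mice_fit_transform <- function(x, max_iter = 20, tol = 1e-3, ridge = 1e-3) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(p))
  miss <- is.na(x)
  n_miss <- colSums(miss)
  if (any(n_miss == nrow(x))) {
    stop("feature(s) entirely missing: drop them before imputation: ",
         paste(colnames(x)[n_miss == nrow(x)], collapse = ", "), call. = FALSE)
  }
  medians <- apply(x, 2, stats::median, na.rm = TRUE)
  order_feats <- colnames(x)[order(n_miss, seq_len(p))]
  order_feats <- order_feats[n_miss[order_feats] > 0]
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  sds[!is.finite(sds) | sds == 0] <- 1

  filled <- x
  for (j in seq_len(p)) filled[miss[, j], j] <- medians[j]

  state <- list(order = order_feats, medians = medians, coefs = list(),
                ridge = ridge, max_iter = max_iter, tol = tol,
                iterations = 0L, converged = length(order_feats) == 0)
  class(state) <- "imputer_state"
  if (!length(order_feats)) {
    return(list(data = filled, state = state))
  }

  for (it in seq_len(max_iter)) {
    max_change <- 0
    for (f in order_feats) {
      obs <- !miss[, f]
      others <- setdiff(colnames(x), f)
      Z <- filled[obs, others, drop = FALSE]
      y <- filled[obs, f]
      fit <- ridge_fit(Z, y, ridge)
      state$coefs[[f]] <- fit
      pred <- ridge_predict(fit, filled[!obs, others, drop = FALSE])
      change <- max(abs(pred - filled[!obs, f]) / sds[f], 0)
      max_change <- max(max_change, change)
      filled[!obs, f] <- pred
    }
    state$iterations <- it
    if (max_change < tol) {
      state$converged <- TRUE
      break
    }
  }
  list(data = filled, state = state)
}

# closed-form ridge with internal standardisation of predictors
ridge_fit <- function(Z, y, ridge) {
  mu <- colMeans(Z)
  sd_ <- apply(Z, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  Zs <- sweep(sweep(Z, 2, mu), 2, sd_, "/")
  ybar <- mean(y)
  lam <- ridge * nrow(Z)
  beta <- solve(crossprod(Zs) + diag(lam, ncol(Zs)), crossprod(Zs, y - ybar))
  list(mu = mu, sd = sd_, beta = drop(beta), intercept = ybar,
       features = colnames(Z))
}

ridge_predict <- function(fit, Znew) {
  if (!nrow(Znew)) return(numeric(0))
  Zs <- sweep(sweep(Znew[, fit$features, drop = FALSE], 2, fit$mu), 2, fit$sd, "/")
  drop(Zs %*% fit$beta) + fit$intercept
}

#' Apply a fitted imputer to new data
#'
#' Imputes missing cells of a held-out table using the train-fitted
#' regression coefficients and medians, without any refitting: missing
#' cells are median-initialised, then the stored per-feature regressions
#' are cycled in the fitted order until the imputed cells stabilise.
#'
#' @param state An `imputer_state` from [mice_fit_transform()].
#' @param x New table with the same columns.
#' @return The completed numeric matrix.
#' @export
apply_imputer <- function(state, x) {
  stopifnot(inherits(state, "imputer_state"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(names(state$medians) %in% colnames(x))) {
    stop("schema mismatch: new table lacks fitted columns", call. = FALSE)
  }
  x <- x[, names(state$medians), drop = FALSE]
  miss <- is.na(x)
  if (!any(miss)) return(x)
  filled <- x
  for (j in colnames(x)) filled[miss[, j], j] <- state$medians[j]
  todo <- intersect(state$order, colnames(x)[colSums(miss) > 0])
  if (!length(todo)) return(filled)
  for (it in seq_len(state$max_iter)) {
    max_change <- 0
    for (f in todo) {
      others <- setdiff(colnames(x), f)
      pred <- ridge_predict(state$coefs[[f]], filled[miss[, f], others, drop = FALSE])
      max_change <- max(max_change, max(abs(pred - filled[miss[, f], f]), 0))
      filled[miss[, f], f] <- pred
    }
    if (max_change < state$tol) break
  }
  filled
}

#' Round integer-typed features after imputation
#'
#' Imputation runs on the linear scale, so integer-typed variables (counts,
#' levels, 0/1 indicators) can come back fractional. This rounds the listed
#' features half-away-from-zero to whole numbers, and additionally clips
#' the listed binary features into `{0, 1}`.
#'
#' @param x Numeric matrix.
#' @param integer_features Column names to round (default: the integer,
#'   binary and category features of [feature_schema()] present in `x`).
#' @param binary_features Columns additionally clipped to `[0, 1]`.
#' @return The matrix with rounded columns.
#' @export
round_integer_features <- function(x,
                                   integer_features = integer_feature_names(),
                                   binary_features = binary_feature_names()) {
  x <- as.matrix(x)
  ints <- intersect(integer_features, colnames(x))
  for (f in ints) {
    v <- x[, f]
    x[, f] <- sign(v) * floor(abs(v) + 0.5)  # round half away from zero
  }
  bins <- intersect(binary_features, colnames(x))
  for (f in bins) x[, f] <- pmin(pmax(x[, f], 0), 1)
  x
}

#' Fit / apply min-max scaling
#'
#' `minmax_fit()` records per-feature minima and maxima of the fitting
#' partition; `minmax_transform()` maps `x` to `(x - min) / (max - min)`.
#' Constant features map to 0. Held-out values outside the fitted range
#' are allowed to fall outside `[0, 1]`; there is no clipping.
#'
#' @param x Numeric matrix (fit: the training partition).
#' @return `minmax_fit()`: a `scaler_state`; `minmax_transform()`: the
#'   scaled matrix.
#' @export
minmax_fit <- function(x) {
  x <- as.matrix(x)
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max)),
            class = "scaler_state")
}

#' @rdname minmax_fit
#' @param state A `scaler_state` from [minmax_fit()].
#' @export
minmax_transform <- function(state, x) {
  stopifnot(inherits(state, "scaler_state"))
  x <- as.matrix(x)[, names(state$min), drop = FALSE]
  rng <- state$max - state$min
  rng[rng == 0] <- 1  # constant features -> 0 after centering
  sweep(sweep(x, 2, state$min), 2, rng, "/")
}

#' Stratified fold assignment
#'
#' Partitions indices into `k` folds preserving the class ratio: within
#' each class the (shuffled) members are dealt round-robin, so every fold's
#' class count is within one patient of every other fold's.
#'
#' @param labels Vector of class labels.
#' @param k Number of folds.
#' @return Integer vector of fold ids (1..k), same length as `labels`.
#' @export
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stop(sprintf("class '%s' has fewer members (%d) than folds (%d)",
                   cl, length(idx), k), call. = FALSE)
    }
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Build the train/test split and cross-validation plan
#'
#' A stratified 80/20 train/test split, `n_repeats` independently shuffled
#' stratified `n_folds`-fold partitions of the training rows for
#' validation, and the fold count for the inner hyperparameter-tuning
#' cross-validation.
#'
#' @param labels Binary outcome labels for all patients.
#' @param seed Integer seed governing all fold randomness.
#' @param test_frac Held-out fraction (default 0.2).
#' @param n_repeats Validation repetitions (default 10).
#' @param n_folds Validation folds per repetition (default 5).
#' @param tune_folds Inner tuning folds (default 3).
#' @return A list of class `split_plan`: `train_idx`, `test_idx`,
#'   `repeats` (a list of fold-id vectors aligned to `train_idx`),
#'   `tune_folds`, `seed`.
#' @export
make_split_plan <- function(labels, seed = 1, test_frac = 0.2,
                            n_repeats = 10, n_folds = 5, tune_folds = 3) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  n <- length(labels)
  test_idx <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_test <- round(length(idx) * test_frac)
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)
  repeats <- lapply(seq_len(n_repeats), function(r) {
    stratified_folds(labels[train_idx], n_folds)
  })
  structure(list(train_idx = train_idx, test_idx = test_idx,
                 repeats = repeats, n_folds = n_folds,
                 tune_folds = tune_folds, seed = as.integer(seed)),
            class = "split_plan")
}

# Full preprocessing fit on a training block; returns frozen states plus
# a transform closure-free application via preprocess_apply().
preprocess_fit <- function(x_train) {
  imp <- mice_fit_transform(x_train)
  xt <- round_integer_features(imp$data)
  sc <- minmax_fit(xt)
  list(imputer = imp$state, scaler = sc,
       train = minmax_transform(sc, xt))
}

preprocess_apply <- function(prep, x_new) {
  xt <- apply_imputer(prep$imputer, x_new)
  xt <- round_integer_features(xt)
  minmax_transform(prep$scaler, xt)
}
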