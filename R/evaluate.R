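# The validation and test-evaluation protocols: repeated stratified
# cross-validation over the training partition with fold-internal
# preprocessing, and the final held-out evaluation.

#' Extract the modelling matrix and outcome from a cohort
#'
#' Pulls the 50 modelling features (see [feature_schema()]) as a numeric
#' matrix, plus the patient-personalized recovery outcome.
#'
#' @param cohort A scored cohort (from [generate_cohort()] or
#'   [read_cohort()] + [score_cohort()]); must contain the feature columns
#'   and `recovered_ppsc`.
#' @return A list with `x` (matrix), `y` (logical), `patient_id`.
#' @export
build_feature_matrix <- function(cohort) {
  feats <- feature_schema()$name
  missing_cols <- setdiff(feats, names(cohort))
  if (length(missing_cols)) {
    stop("cohort lacks feature columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(cohort[, feats])
  storage.mode(x) <- "double"
  y <- as.logical(cohort$recovered_ppsc)
  if (anyNA(y)) stop("cohort has missing outcome labels", call. = FALSE)
  list(x = x, y = y, patient_id = cohort$patient_id)
}

# evaluate all models + ensemble on one (train, eval) pair, preprocessing
# fitted on the training block only
evaluate_cycle <- function(x_tr, y_tr, x_ev, y_ev, grids, tune_folds, seed) {
  prep <- preprocess_fit(x_tr)
  xe <- preprocess_apply(prep, x_ev)
  models <- fit_model_zoo(prep$train, y_tr, grids, tune_folds, seed)
  out <- lapply(models, function(m) threshold_metrics(predict_prob(m, xe), y_ev))
  sv <- soft_vote(models, xe)
  out$soft_voting <- threshold_metrics(sv$prob, y_ev)
  do.call(rbind, out)
}

#' Run the repeated cross-validation protocol
#'
#' For every (repetition, fold) cycle of the plan: fit the imputer and
#' scaler on the sub-training rows, transform the validation fold, tune
#' and fit all eight families plus the soft-voting ensemble, and score the
#' fold. Reports, per model, the mean of each metric over all cycles and
#' a percentile interval of the cycle AUROCs.
#'
#' @param x Numeric feature matrix for the full cohort (may contain `NA`).
#' @param y Logical outcome vector.
#' @param plan A [make_split_plan()].
#' @param grids Model grids ([default_grids()]); the compact single-point
#'   grids by default.
#' @param conf Confidence level of the percentile interval.
#' @return A list of class `eval_report` with `phase = "validation"`,
#'   `summary` (data.frame model x metric), `auroc_ci`, and `cycles` (the
#'   per-cycle metric array).
#' @export
run_validation <- function(x, y, plan, grids = default_grids(FALSE),
                           conf = 0.95) {
  stopifnot(inherits(plan, "split_plan"))
  tr <- plan$train_idx
  cycles <- list()
  for (r in seq_along(plan$repeats)) {
    fold <- plan$repeats[[r]]
    for (f in seq_len(plan$n_folds)) {
      sub <- tr[fold != f]
      val <- tr[fold == f]
      seed <- plan$seed + 1000L * r + f
      cycles[[length(cycles) + 1L]] <-
        evaluate_cycle(x[sub, , drop = FALSE], y[sub],
                       x[val, , drop = FALSE], y[val],
                       grids, plan$tune_folds, seed)
    }
  }
  arr <- simplify2array(cycles)  # model x metric x cycle
  summary <- as.data.frame(apply(arr, c(1, 2), mean, na.rm = TRUE))
  a <- (1 - conf) / 2
  auroc_ci <- t(apply(arr[, "auroc", , drop = FALSE], 1, function(v) {
    stats::quantile(v, c(a, 1 - a), na.rm = TRUE)
  }))
  structure(list(phase = "validation", summary = summary,
                 auroc_ci = auroc_ci, n_cycles = length(cycles),
                 cycles = arr),
            class = "eval_report")
}

#' Run the held-out test evaluation
#'
#' Preprocessing is fitted on the full training partition and applied,
#' frozen, to the untouched test partition; all families are tuned on the
#' training partition, fitted, and scored on the test rows together with
#' the soft-voting ensemble. The best model is the one with the highest
#' test AUROC.
#'
#' @inheritParams run_validation
#' @param n_boot Bootstrap resamples for the test AUROC interval.
#' @return A list of class `eval_report` with `phase = "test"`, `summary`,
#'   `auroc_ci`, `best_model` (name), `models` (fitted, including
#'   `soft_voting`), `prep` (frozen preprocessing states), `x_test`
#'   (preprocessed test matrix), `y_test`, and `probs` (per-model test
#'   probabilities).
#' @export
run_test_evaluation <- function(x, y, plan, grids = default_grids(FALSE),
                                n_boot = 2000, conf = 0.95) {
  stopifnot(inherits(plan, "split_plan"))
  tr <- plan$train_idx; te <- plan$test_idx
  prep <- preprocess_fit(x[tr, , drop = FALSE])
  x_test <- preprocess_apply(prep, x[te, , drop = FALSE])
  models <- fit_model_zoo(prep$train, y[tr], grids, plan$tune_folds,
                          seed = plan$seed + 77L)
  probs <- lapply(models, function(m) predict_prob(m, x_test))
  probs$soft_voting <- soft_vote(models, x_test)$prob
  summary <- do.call(rbind, lapply(probs, threshold_metrics,
                                   labels = y[te]))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(plan$seed + 999L)
  ci <- t(vapply(probs, function(p) {
    auroc_ci(p, y[te], n_boot = n_boot, conf = conf)$ci
  }, numeric(2)))
  colnames(ci) <- paste0(c("lo", "hi"), format(conf))
  best <- rownames(summary)[which.max(summary[, "auroc"])]
  all_models <- c(models, list(soft_voting = soft_vote_fit(models)))
  structure(list(phase = "test", summary = as.data.frame(summary),
                 auroc_ci = ci, best_model = best, models = all_models,
                 prep = prep, x_test = x_test, y_test = y[te],
                 x_train = prep$train, y_train = y[tr], probs = probs),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %s phase%s>\n", x$phase,
              if (!is.null(x$n_cycles)) sprintf(", %d cycles", x$n_cycles) else ""))
  print(round(as.matrix(x$summary), 3))
  if (!is.null(x$best_model)) cat("best model:", x$best_model, "\n")
  invisible(x)
}
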