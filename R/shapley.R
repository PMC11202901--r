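# Model-agnostic Shapley attribution by permutation sampling, on the
# positive-class probability scale, with mean-|value| feature ranking.

#' Shapley feature attributions by permutation sampling
#'
#' Estimates, for every row of `x`, the Shapley value of each feature with
#' respect to the model's positive-class probability: features enter in a
#' random order and each feature is credited with the change in prediction
#' when its value replaces the background value. Absent features take
#' their values from a background row drawn per permutation, so for every
#' permutation the per-feature contributions telescope exactly to
#' `f(x) - f(z)`; averaged over permutations, the attributions of a row
#' sum exactly to its prediction minus the row's `base` value (the mean
#' prediction of the sampled background rows) -- the local-accuracy
#' property.
#'
#' @param model A `ppsc_model` / `ppsc_ensemble`, or any object accepted
#'   by `predict_fun`.
#' @param x Numeric matrix of rows to explain.
#' @param background Numeric matrix of background rows (typically a seeded
#'   subsample of the training partition).
#' @param n_perm Number of sampled permutations per row (default 40).
#' @param seed Integer seed.
#' @param predict_fun Function `(model, matrix) -> numeric`; defaults to
#'   [predict_prob()].
#' @return A list of class `shap_summary`: `values` (rows x features),
#'   `base` (per-row baseline), `pred` (per-row prediction), `mean_abs`
#'   (named, per-feature mean absolute attribution), `ranking` (feature
#'   names, descending mean |value|).
#' @export
shapley_attributions <- function(model, x, background, n_perm = 40, seed = 1,
                                 predict_fun = predict_prob) {
  x <- as.matrix(x); background <- as.matrix(background)
  if (!nrow(background)) stop("background sample is empty", call. = FALSE)
  stopifnot(ncol(x) == ncol(background), n_perm >= 1)
  n <- nrow(x); p <- ncol(x)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  phi <- matrix(0, n, p, dimnames = list(NULL, colnames(x)))
  base <- numeric(n)
  for (m in seq_len(n_perm)) {
    perm <- sample.int(p)
    z_idx <- sample.int(nrow(background), n, replace = TRUE)
    z <- background[z_idx, , drop = FALSE]
    # build the p+1 step matrices for all rows at once:
    # step k has the first k features (in permutation order) from x
    big <- matrix(0, n * (p + 1), p)
    cur <- z
    big[seq_len(n), ] <- cur
    for (k in seq_len(p)) {
      j <- perm[k]
      cur[, j] <- x[, j]
      big[k * n + seq_len(n), ] <- cur
    }
    colnames(big) <- colnames(x)
    preds <- predict_fun(model, big)
    pm <- matrix(preds, n, p + 1)
    base <- base + pm[, 1]
    contrib <- pm[, -1, drop = FALSE] - pm[, -(p + 1), drop = FALSE]
    phi[, perm] <- phi[, perm] + contrib
  }
  phi <- phi / n_perm
  base <- base / n_perm
  pred <- predict_fun(model, x)
  mean_abs <- colMeans(abs(phi))
  structure(list(values = phi, base = base, pred = pred,
                 mean_abs = mean_abs,
                 ranking = names(sort(mean_abs, decreasing = TRUE))),
            class = "shap_summary")
}

#' Rank features by mean absolute attribution
#'
#' Produces the top-k table behind a beeswarm-style attribution summary:
#' per feature, the mean absolute Shapley value, its rank, and a direction
#' summary (the correlation between feature value and attribution, so a
#' negative sign means high feature values push the prediction down).
#'
#' @param summary A `shap_summary` from [shapley_attributions()].
#' @param x The matrix that was explained (for the direction summary and
#'   plot data); optional.
#' @param k Number of top features (default 20, capped at the feature
#'   count).
#' @return A list with `table` (data.frame: feature, mean_abs_shap, rank,
#'   direction) and `plot_data` (long data.frame: feature, rank,
#'   shap_value, feature_value) for the top-k features.
#' @export
rank_attributions <- function(summary, x = NULL, k = 20) {
  stopifnot(inherits(summary, "shap_summary"))
  k <- min(k, length(summary$mean_abs))
  top <- summary$ranking[seq_len(k)]
  direction <- vapply(top, function(f) {
    if (is.null(x)) return(NA_real_)
    v <- x[, f]
    if (stats::sd(v) == 0 || stats::sd(summary$values[, f]) == 0) return(0)
    stats::cor(v, summary$values[, f])
  }, numeric(1))
  table <- data.frame(feature = top,
                      mean_abs_shap = unname(summary$mean_abs[top]),
                      rank = seq_len(k),
                      direction = unname(direction),
                      stringsAsFactors = FALSE)
  plot_data <- NULL
  if (!is.null(x)) {
    plot_data <- do.call(rbind, lapply(seq_len(k), function(i) {
      f <- top[i]
      data.frame(feature = f, rank = i,
                 shap_value = summary$values[, f],
                 feature_value = x[, f], stringsAsFactors = FALSE)
    }))
  }
  list(table = table, plot_data = plot_data)
}
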