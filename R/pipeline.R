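# End-to-end pipeline: simulate (or load) a cohort, run the exclusion
# cascade, score both criteria variants, compute the assessment shift and
# group comparisons, run the modelling protocol, and attribute the best
# model's predictions.

#' Run the full analysis pipeline
#'
#' Sequences all package stages and writes their artifacts into a run
#' directory: `cohort.csv`, `exclusion.json`, `scores.csv`, `shift.json`,
#' `group_comparison.csv`, `validation.csv`, `test_report.csv`,
#' `shap_summary.csv`, and `run_info.json` (seed, configuration echo,
#' package version). Every stage can also be run on its own through the
#' exported stage functions.
#'
#' @param out_dir Output directory (created if absent).
#' @param cohort An existing cohort data.frame, or `NULL` to simulate one
#'   with `gen_config`.
#' @param gen_config A [generator_config()] used when `cohort` is `NULL`.
#' @param seed Master seed; fans out to the split plan, model fits,
#'   bootstrap and attribution.
#' @param variant `"both"` (default) runs both criteria variants and the
#'   shift comparison; `"ppsc"` or `"traditional"` skips the shift stage.
#' @param grids Model grids; compact single-point grids by default.
#' @param n_repeats,n_folds Validation protocol size (defaults 10 x 5).
#' @param run_validation_stage Set `FALSE` to skip the repeated-validation
#'   stage (the test evaluation always runs).
#' @param shap_n_perm Permutations for the attribution stage.
#' @param n_boot Bootstrap resamples for test AUROC intervals.
#' @return Invisibly, a list with every stage result (`cohort`,
#'   `exclusion`, `scores`, `shift`, `comparison`, `validation`, `test`,
#'   `attribution`, `paths`).
#' @export
run_pipeline <- function(out_dir, cohort = NULL,
                         gen_config = generator_config(), seed = 1,
                         variant = c("both", "ppsc", "traditional"),
                         grids = default_grids(FALSE),
                         n_repeats = 10, n_folds = 5,
                         run_validation_stage = TRUE,
                         shap_n_perm = 40, n_boot = 2000) {
  variant <- match.arg(variant)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) message("[ppsc] ", sprintf(...))

  if (is.null(cohort)) {
    log_line("simulating cohort (n = %d, seed = %d)",
             gen_config$n_patients, gen_config$seed)
    cohort <- generate_cohort(gen_config)
  }
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  log_line("applying exclusion cascade")
  casc <- apply_exclusion_cascade(cohort)
  jsonlite::write_json(list(initial_n = casc$report$initial_n,
                            excluded = as.list(casc$report$excluded),
                            final_n = casc$report$final_n),
                       file.path(out_dir, "exclusion.json"), auto_unbox = TRUE)
  kept <- casc$cohort

  log_line("scoring recovery (variant = %s)", variant)
  scores <- score_cohort(kept, if (variant == "both") "both" else variant)
  utils::write.csv(scores, file.path(out_dir, "scores.csv"), row.names = FALSE)

  shift <- NULL
  if (variant == "both") {
    shift <- assessment_shift(scores[scores$variant == "traditional", ],
                              scores[scores$variant == "ppsc", ])
    chi <- chi_square_2x2(shift$table)
    jsonlite::write_json(list(table = shift$table, n_up = shift$n_up,
                              n_down = shift$n_down, n_changed = shift$n_changed,
                              chi_square = chi$statistic, p_value = chi$p_value),
                         file.path(out_dir, "shift.json"),
                         auto_unbox = TRUE, matrix = "rowmajor")
  } else {
    log_line("shift stage skipped: single variant requested")
  }

  # outcome: patient-personalized recovery (recomputed, not the stored column)
  ppsc_scores <- scores[scores$variant == ifelse(variant == "traditional",
                                                 "traditional", "ppsc"), ]
  kept$recovered_ppsc <- as.integer(
    ppsc_scores$recovered[match(kept$patient_id, ppsc_scores$patient_id)])

  log_line("comparing recovered vs non-recovered groups")
  comparison <- compare_groups(kept)
  utils::write.csv(comparison, file.path(out_dir, "group_comparison.csv"),
                   row.names = FALSE)

  fm <- build_feature_matrix(kept)
  plan <- make_split_plan(fm$y, seed = seed, n_repeats = n_repeats,
                          n_folds = n_folds)

  validation <- NULL
  if (run_validation_stage) {
    log_line("running %d x %d repeated validation", n_repeats, n_folds)
    validation <- run_validation(fm$x, fm$y, plan, grids)
    utils::write.csv(cbind(model = rownames(validation$summary),
                           validation$summary),
                     file.path(out_dir, "validation.csv"), row.names = FALSE)
  }

  log_line("running test evaluation")
  test <- run_test_evaluation(fm$x, fm$y, plan, grids, n_boot = n_boot)
  utils::write.csv(cbind(model = rownames(test$summary), test$summary,
                         auroc_ci_lo = test$auroc_ci[, 1],
                         auroc_ci_hi = test$auroc_ci[, 2]),
                   file.path(out_dir, "test_report.csv"), row.names = FALSE)

  log_line("attributing best model (%s)", test$best_model)
  bg_idx <- local({
    set.seed(seed + 13L)
    sample(nrow(test$x_train), min(100, nrow(test$x_train)))
  })
  shap <- shapley_attributions(test$models[[test$best_model]], test$x_test,
                               test$x_train[bg_idx, , drop = FALSE],
                               n_perm = shap_n_perm, seed = seed + 29L)
  ranked <- rank_attributions(shap, test$x_test, k = 20)
  utils::write.csv(ranked$table, file.path(out_dir, "shap_summary.csv"),
                   row.names = FALSE)

  jsonlite::write_json(
    list(seed = seed, variant = variant,
         n_patients = nrow(cohort), n_retained = nrow(kept),
         package_version = as.character(utils::packageVersion("ppsc")),
         best_model = test$best_model),
    file.path(out_dir, "run_info.json"), auto_unbox = TRUE)

  invisible(list(cohort = cohort, exclusion = casc$report, scores = scores,
                 shift = shift, comparison = comparison,
                 validation = validation, test = test,
                 attribution = list(summary = shap, ranked = ranked),
                 paths = out_dir))
}
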