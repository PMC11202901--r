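# Cohort-level statistics: the sequential exclusion cascade, the
# assessment-shift comparison between criteria variants, and the
# recovered vs non-recovered group comparison table.

#' Apply the sequential exclusion cascade to a raw cohort
#'
#' Patients are excluded by five ordered rules, each patient being removed
#' at the first rule it violates: (1) the record duplicates another
#' patient's record; (2) missing thresholds in the affected-ear audiogram
#' measured one month post-treatment; (3) missing thresholds in the
#' initial-visit audiograms of either ear; (4) bilateral disease; (5) the
#' initial affected-ear audiogram contains no qualifying impaired run of at
#' least `min_run_length` contiguous frequencies at or above the cutoff.
#'
#' @param cohort A raw cohort data.frame (see [generate_cohort()]); must
#'   contain the audiogram columns, a `bilateral` 0/1 column and a
#'   `patient_id` column.
#' @param config A [detection_config()] for rule 5.
#' @return A list with `cohort` (the retained rows) and `report`, a list of
#'   class `exclusion_report` with `initial_n`, the named per-rule `excluded`
#'   counts, and `final_n`.
#' @export
apply_exclusion_cascade <- function(cohort, config = detection_config()) {
  rules <- c("duplicate_record", "missing_month1_pta", "missing_initial_pta",
             "bilateral", "no_qualifying_run")
  n0 <- nrow(cohort)
  excluded <- setNames(integer(length(rules)), rules)
  keep <- rep(TRUE, n0)

  feature_cols <- setdiff(names(cohort), c("patient_id", "plant"))
  dup <- duplicated(cohort[, feature_cols, drop = FALSE])
  excluded["duplicate_record"] <- sum(dup & keep)
  keep <- keep & !dup

  m1 <- rowSums(is.na(audiogram_matrix(cohort, "aff", "t1"))) > 0
  excluded["missing_month1_pta"] <- sum(m1 & keep)
  keep <- keep & !m1

  t0 <- rowSums(is.na(audiogram_matrix(cohort, "aff", "t0"))) > 0 |
        rowSums(is.na(audiogram_matrix(cohort, "una", "t0"))) > 0
  excluded["missing_initial_pta"] <- sum(t0 & keep)
  keep <- keep & !t0

  bil <- !is.na(cohort$bilateral) & cohort$bilateral == 1
  excluded["bilateral"] <- sum(bil & keep)
  keep <- keep & !bil

  aff0 <- audiogram_matrix(cohort, "aff", "t0")
  norun <- vapply(seq_len(n0), function(i) {
    is.null(detect_impaired_range(aff0[i, ], config))
  }, logical(1))
  excluded["no_qualifying_run"] <- sum(norun & keep)
  keep <- keep & !norun

  report <- structure(list(initial_n = n0, excluded = excluded,
                           final_n = sum(keep)),
                      class = "exclusion_report")
  list(cohort = cohort[keep, , drop = FALSE], report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion cascade:", x$initial_n, "->", x$final_n, "patients\n")
  for (r in names(x$excluded)) {
    cat(sprintf("  - %-20s %d\n", r, x$excluded[[r]]))
  }
  invisible(x)
}

#' Tabulate the assessment shift between two criteria variants
#'
#' Cross-tabulates the recovered flag of the same patients under the
#' traditional and the patient-personalized criteria, and counts the
#' reclassifications in each direction.
#'
#' @param traditional,ppsc Score tables from [score_cohort()] (or any
#'   data.frames with `patient_id` and logical `recovered`), covering the
#'   same patients.
#' @return A list of class `shift_table`: `table` (2x2 matrix of
#'   recovered/non-recovered counts by variant), `n_up` (non-recovered ->
#'   recovered), `n_down` (recovered -> non-recovered), `n_changed`, `n`.
#' @export
assessment_shift <- function(traditional, ppsc) {
  ord <- match(traditional$patient_id, ppsc$patient_id)
  if (anyNA(ord) || nrow(traditional) != nrow(ppsc)) {
    stop("the two score tables must cover the same patients", call. = FALSE)
  }
  rt <- traditional$recovered
  rp <- ppsc$recovered[ord]
  tab <- rbind(traditional = c(recovered = sum(rt), non_recovered = sum(!rt)),
               ppsc = c(recovered = sum(rp), non_recovered = sum(!rp)))
  out <- structure(list(table = tab,
                        n_up = sum(!rt & rp),
                        n_down = sum(rt & !rp),
                        n_changed = sum(rt != rp),
                        n = length(rt)),
                   class = "shift_table")
  stopifnot(out$table["ppsc", "recovered"] ==
              out$table["traditional", "recovered"] - out$n_down + out$n_up)
  out
}

#' @export
print.shift_table <- function(x, ...) {
  print(x$table)
  cat(sprintf("reclassified: %d up, %d down, %d total of %d patients\n",
              x$n_up, x$n_down, x$n_changed, x$n))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table, without continuity correction
#'
#' The shift in the recovery distribution between the two criteria variants
#' is tested by treating the two assessments as two samples: a Pearson
#' chi-square on the 2x2 variant-by-status table with 1 degree of freedom
#' and no continuity correction. For a paired alternative that respects the
#' fact that both assessments grade the same patients, see
#' [mcnemar_shift()].
#'
#' @param table A 2x2 matrix of non-negative counts.
#' @return A list with `statistic`, `p_value`, `df`.
#' @export
#' @examples
#' chi_square_2x2(rbind(c(247, 334), c(220, 361)))
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("2x2 table has a zero marginal", call. = FALSE)
  }
  ht <- stats::chisq.test(table, correct = FALSE)
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       df = unname(ht$parameter))
}

#' McNemar test on paired recovery assessments
#'
#' Paired alternative to [chi_square_2x2()]: tests whether the two
#' reclassification directions are balanced, using only the discordant
#' patients. Offered as an extra view of the shift; the primary shift test
#' in this package is the unpaired Pearson chi-square.
#'
#' @param shift A `shift_table` from [assessment_shift()].
#' @param correct Apply the continuity correction (default `TRUE`, as in
#'   [stats::mcnemar.test()]).
#' @return A list with `statistic`, `p_value`, `df`.
#' @export
mcnemar_shift <- function(shift, correct = TRUE) {
  stopifnot(inherits(shift, "shift_table"))
  b <- shift$n_down; c <- shift$n_up
  stat <- if (correct) (abs(b - c) - 1)^2 / (b + c) else (b - c)^2 / (b + c)
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
       df = 1)
}

#' Compare recovered and non-recovered patients variable by variable
#'
#' For each requested variable, summarises the two outcome groups and tests
#' for a difference at two-sided alpha = 0.05. Continuous variables are
#' gated by a Shapiro-Wilk normality test on each group: when both groups
#' look normal (p >= 0.05) the summary is mean (SD) and the test an
#' independent-samples t-test; otherwise the summary is median (Q1, Q3) and
#' the test Mann-Whitney U. Categorical variables are summarised as count
#' (percent) and tested by Pearson chi-square, falling back to Fisher's
#' exact test when any expected cell count is below 5. Constant variables
#' are summarised but their test is skipped with a reason. No multiplicity
#' correction is applied.
#'
#' @param cohort A cohort data.frame containing `vars` and the grouping
#'   column.
#' @param group Name of a logical/0-1 column defining the groups (default
#'   the patient-personalized recovered flag).
#' @param vars Character vector of variable names; defaults to all feature
#'   columns present (see [feature_schema()]).
#' @return A data.frame with one row per variable: group summaries, missing
#'   counts, test name and p-value.
#' @export
compare_groups <- function(cohort, group = "recovered_ppsc", vars = NULL) {
  stopifnot(group %in% names(cohort))
  g <- as.logical(cohort[[group]])
  if (is.null(vars)) {
    vars <- intersect(feature_schema()$name, names(cohort))
  }
  one <- function(v) {
    x <- cohort[[v]]
    miss0 <- sum(is.na(x[!g])); miss1 <- sum(is.na(x[g]))
    x0 <- x[!g & !is.na(x)]; x1 <- x[g & !is.na(x)]
    schema <- feature_schema()
    type <- schema$type[match(v, schema$name)]
    categorical <- !is.na(type) && type %in% c("binary", "category")
    if (length(unique(c(x0, x1))) <= 1) {
      return(data.frame(variable = v, type = if (categorical) "categorical" else "continuous",
                        summary_nonrecovery = format_summary(x0, categorical),
                        summary_recovery = format_summary(x1, categorical),
                        test = "skipped (constant)", p_value = NA_real_,
                        missing_nonrecovery = miss0, missing_recovery = miss1,
                        stringsAsFactors = FALSE))
    }
    if (categorical) {
      tab <- table(factor(c(x0, x1)), rep(c(FALSE, TRUE), c(length(x0), length(x1))))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        # exact test can exhaust its network workspace on many-level tables;
        # fall back to the asymptotic test there
        ft <- tryCatch(stats::fisher.test(tab, workspace = 1e7),
                       error = function(e) NULL)
        if (!is.null(ft)) {
          p <- ft$p.value
          test <- "Fisher exact"
        } else {
          p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
          test <- "chi-square (sparse)"
        }
      } else {
        p <- stats::chisq.test(tab, correct = FALSE)$p.value
        test <- "chi-square"
      }
      data.frame(variable = v, type = "categorical",
                 summary_nonrecovery = format_summary(x0, TRUE),
                 summary_recovery = format_summary(x1, TRUE),
                 test = test, p_value = p,
                 missing_nonrecovery = miss0, missing_recovery = miss1,
                 stringsAsFactors = FALSE)
    } else {
      normal <- function(z) {
        if (length(z) < 3 || length(unique(z)) < 3) return(FALSE)
        stats::shapiro.test(if (length(z) > 5000) sample(z, 5000) else z)$p.value >= 0.05
      }
      if (normal(x0) && normal(x1)) {
        p <- stats::t.test(x0, x1)$p.value
        test <- "t-test"
        s0 <- sprintf("%.2f (%.2f)", mean(x0), stats::sd(x0))
        s1 <- sprintf("%.2f (%.2f)", mean(x1), stats::sd(x1))
      } else {
        p <- stats::wilcox.test(x0, x1, exact = FALSE)$p.value
        test <- "Mann-Whitney U"
        s0 <- format_summary(x0, FALSE); s1 <- format_summary(x1, FALSE)
      }
      data.frame(variable = v, type = "continuous",
                 summary_nonrecovery = s0, summary_recovery = s1,
                 test = test, p_value = p,
                 missing_nonrecovery = miss0, missing_recovery = miss1,
                 stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, lapply(vars, one))
  rownames(out) <- NULL
  out
}

format_summary <- function(x, categorical) {
  if (!length(x)) return("-")
  if (categorical) {
    lv <- sort(unique(x))
    if (length(lv) <= 2 && all(lv %in% c(0, 1))) {
      sprintf("%d (%.2f%%)", sum(x == 1), 100 * mean(x == 1))
    } else {
      paste(sprintf("%s:%d", lv, as.integer(table(factor(x, levels = lv)))),
            collapse = " ")
    }
  } else {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    sprintf("%.2f (%.2f, %.2f)", q[2], q[1], q[3])
  }
}
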