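# Siegel recovery grading, in the traditional fixed-band variant and the
# patient-personalized variant that scores over the individually impaired
# frequency range.

#' Siegel grading thresholds
#'
#' The dB cut points of the four-class recovery grading. Complete recovery:
#' post-treatment mean at or below `complete_max_db`. Partial: gain above
#' `gain_min_db` and post-treatment mean above `complete_max_db` but within
#' `partial_max_db`. Slight: gain above `gain_min_db` and post-treatment
#' mean above `partial_max_db` but within `slight_max_db`. Otherwise: none.
#'
#' @param complete_max_db,gain_min_db,partial_max_db,slight_max_db Cut
#'   points in dB; defaults 25, 15, 45, 75.
#' @return A list of class `siegel_thresholds`.
#' @export
siegel_thresholds <- function(complete_max_db = 25, gain_min_db = 15,
                              partial_max_db = 45, slight_max_db = 75) {
  stopifnot(complete_max_db < partial_max_db, partial_max_db < slight_max_db,
            complete_max_db > 0, gain_min_db > 0)
  structure(list(complete_max_db = complete_max_db, gain_min_db = gain_min_db,
                 partial_max_db = partial_max_db, slight_max_db = slight_max_db),
            class = "siegel_thresholds")
}

#' Siegel recovery classes
#' @return Character vector of the four classes, best to worst.
#' @export
siegel_classes <- function() c("complete", "partial", "slight", "none")

#' Classify recovery from pre- and post-treatment mean thresholds
#'
#' Applies the Siegel grading to a pair of mean pure-tone thresholds.
#' Hearing gain is `initial_mean_db - month1_mean_db` (positive =
#' improvement). Complete recovery requires only a post-treatment mean at
#' or below 25 dB, regardless of gain. Partial and slight recovery require
#' a gain strictly greater than 15 dB together with a post-treatment mean
#' in (25, 45] and (45, 75] respectively; everything else, including a
#' post-treatment mean above 75 dB, is graded none. A gain of exactly
#' 15 dB does not grant recovery. Complete and partial count as recovered.
#'
#' Vectorized over the two mean arguments.
#'
#' @param initial_mean_db,month1_mean_db Mean thresholds (dB HL) at the
#'   initial visit and one month post-treatment; must be finite.
#' @param thresholds A [siegel_thresholds()].
#' @return A data.frame of class `siegel_result` with columns
#'   `initial_mean_db`, `month1_mean_db`, `gain_db`, `class`, `recovered`.
#' @export
#' @examples
#' siegel_classify(55, 30)      # gain 25 dB, post 30 dB -> partial
#' siegel_classify(63.75, 47.5) # gain 16.25 dB, post 47.5 dB -> slight
siegel_classify <- function(initial_mean_db, month1_mean_db,
                            thresholds = siegel_thresholds()) {
  stopifnot(inherits(thresholds, "siegel_thresholds"),
            length(initial_mean_db) == length(month1_mean_db))
  if (any(!is.finite(initial_mean_db)) || any(!is.finite(month1_mean_db))) {
    stop("mean thresholds must be finite", call. = FALSE)
  }
  th <- thresholds
  gain <- initial_mean_db - month1_mean_db
  m1 <- month1_mean_db
  klass <- ifelse(m1 <= th$complete_max_db, "complete",
           ifelse(gain > th$gain_min_db & m1 <= th$partial_max_db, "partial",
           ifelse(gain > th$gain_min_db & m1 <= th$slight_max_db, "slight",
                  "none")))
  out <- data.frame(initial_mean_db = initial_mean_db,
                    month1_mean_db = month1_mean_db,
                    gain_db = gain,
                    class = klass,
                    recovered = klass %in% c("complete", "partial"),
                    stringsAsFactors = FALSE)
  class(out) <- c("siegel_result", "data.frame")
  out
}

#' Assess one patient under a chosen criteria variant
#'
#' Computes the pre- and post-treatment mean thresholds of the affected ear
#' over the variant's frequency set and applies [siegel_classify()]. The
#' `"ppsc"` variant (patient-personalized) averages over the impaired range
#' detected on the initial affected-ear audiogram; the `"traditional"`
#' variant averages over the fixed 0.5-3 kHz band.
#'
#' @param aff_t0,aff_t1 Affected-ear audiograms at the initial visit and one
#'   month post-treatment (numeric length-8 vectors).
#' @param variant `"ppsc"` or `"traditional"`.
#' @param config A [detection_config()], used by the `"ppsc"` variant.
#' @param thresholds A [siegel_thresholds()].
#' @return A one-row `siegel_result` with an added `variant` column.
#' @export
assess_patient <- function(aff_t0, aff_t1,
                           variant = c("ppsc", "traditional"),
                           config = detection_config(),
                           thresholds = siegel_thresholds()) {
  variant <- match.arg(variant)
  if (variant == "ppsc") {
    rng <- detect_impaired_range(aff_t0, config)
    if (is.null(rng)) {
      stop("no qualifying impaired range; patient cannot be assessed under ppsc",
           call. = FALSE)
    }
    m0 <- mean_pta(aff_t0, rng)
    m1 <- mean_pta(aff_t1, rng)
  } else {
    m0 <- mean_pta(aff_t0, freqs = traditional_band())
    m1 <- mean_pta(aff_t1, freqs = traditional_band())
  }
  res <- siegel_classify(m0, m1, thresholds)
  res$variant <- variant
  res[, c("variant", setdiff(names(res), "variant"))]
}

#' Score a whole cohort under one or both criteria variants
#'
#' Applies [assess_patient()] to every row of a cohort table (see
#' [generate_cohort()] / [read_cohort()] for the column layout).
#'
#' @param cohort A cohort data.frame with the `ac_aff_<freq>_t0/t1`
#'   threshold columns and a `patient_id` column.
#' @param variant `"ppsc"`, `"traditional"`, or `"both"`.
#' @param config A [detection_config()].
#' @param thresholds A [siegel_thresholds()].
#' @return A data.frame with one row per patient and variant: `patient_id`,
#'   `variant`, `initial_mean_db`, `month1_mean_db`, `gain_db`, `class`,
#'   `recovered`.
#' @export
score_cohort <- function(cohort, variant = c("ppsc", "traditional", "both"),
                         config = detection_config(),
                         thresholds = siegel_thresholds()) {
  variant <- match.arg(variant)
  variants <- if (variant == "both") c("traditional", "ppsc") else variant
  aff_t0 <- audiogram_matrix(cohort, "aff", "t0")
  aff_t1 <- audiogram_matrix(cohort, "aff", "t1")
  out <- lapply(variants, function(v) {
    rows <- lapply(seq_len(nrow(cohort)), function(i) {
      assess_patient(aff_t0[i, ], aff_t1[i, ], variant = v,
                     config = config, thresholds = thresholds)
    })
    res <- do.call(rbind, rows)
    res <- cbind(patient_id = cohort$patient_id, res)
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Extract an n x 8 threshold matrix from cohort columns ac_<ear>_<freq>_<tp>.
audiogram_matrix <- function(cohort, ear = c("aff", "una"), tp = c("t0", "t1")) {
  ear <- match.arg(ear); tp <- match.arg(tp)
  cols <- audiogram_cols(ear, tp)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols)) {
    stop("cohort lacks threshold columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  as.matrix(cohort[, cols])
}

audiogram_cols <- function(ear, tp) {
  sprintf("ac_%s_%s_%s", ear, format(freq_grid(), trim = TRUE, drop0trailing = TRUE), tp)
}
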