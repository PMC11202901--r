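# Core audiometry: the fixed frequency grid, impaired-run detection,
# range-restricted pure-tone averaging, severity bands and audiogram shapes.

#' The standard audiometric frequency grid
#'
#' Pure-tone thresholds are measured at eight standard frequencies.
#' All audiograms handled by this package are numeric vectors of length 8
#' aligned to this grid.
#'
#' @return Numeric vector of the 8 test frequencies in kHz.
#' @export
#' @examples
#' freq_grid()
freq_grid <- function() {
  c(0.125, 0.25, 0.5, 1, 2, 3, 4, 8)
}

#' Frequencies of the traditional fixed assessment band
#'
#' The conventional recovery assessment averages thresholds over
#' 0.5, 1, 2 and 3 kHz for every patient, regardless of where the
#' individual hearing loss sits.
#'
#' @return Numeric vector of 4 frequencies in kHz.
#' @export
traditional_band <- function() {
  c(0.5, 1, 2, 3)
}

#' Configuration for impaired-range detection
#'
#' Sudden sensorineural hearing loss is defined by a loss of at least
#' `cutoff_db` (30 dB HL) over at least `min_run_length` (3) contiguous
#' test frequencies.
#'
#' @param cutoff_db Impairment threshold in dB HL; must be positive.
#' @param min_run_length Minimum number of contiguous qualifying
#'   frequencies; must be at least 1.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(cutoff_db = 30, min_run_length = 3) {
  stopifnot(is.numeric(cutoff_db), length(cutoff_db) == 1, cutoff_db > 0,
            is.numeric(min_run_length), length(min_run_length) == 1,
            min_run_length >= 1)
  structure(list(cutoff_db = cutoff_db,
                 min_run_length = as.integer(min_run_length)),
            class = "detection_config")
}

# Validate an 8-threshold vector; NAs allowed unless allow_na = FALSE.
validate_thresholds <- function(x, allow_na = TRUE, what = "thresholds") {
  if (!is.numeric(x) || length(x) != length(freq_grid())) {
    stop(sprintf("`%s` must be a numeric vector of length %d (one per grid frequency)",
                 what, length(freq_grid())), call. = FALSE)
  }
  if (!allow_na && anyNA(x)) {
    stop(sprintf("`%s` must not contain missing values", what), call. = FALSE)
  }
  ok <- !is.na(x)
  if (any(x[ok] < -10 | x[ok] > 120)) {
    stop(sprintf("`%s` must lie in [-10, 120] dB HL", what), call. = FALSE)
  }
  invisible(x)
}

#' Detect the patient-specific impaired frequency range
#'
#' Finds contiguous runs of frequencies whose threshold is at or above the
#' impairment cutoff and returns the selected qualifying run: the longest
#' run of length `>= min_run_length`, ties broken towards the lowest
#' frequency. Isolated qualifying frequencies outside the selected run
#' (for example a single impaired 8 kHz) are excluded, because a single
#' frequency does not constitute the contiguous loss that defines the
#' condition. Missing thresholds are treated as non-qualifying positions.
#'
#' @param thresholds Numeric vector of 8 thresholds in dB HL aligned to
#'   [freq_grid()]; `NA` allowed.
#' @param config A [detection_config()].
#' @return A list of class `impaired_range` with elements `start` (1-based
#'   index into the grid), `length`, and `freqs` (the covered frequencies in
#'   kHz), or `NULL` when no run qualifies.
#' @export
#' @examples
#' # low-frequency loss plus an isolated impaired 8 kHz: 8 kHz is excluded
#' detect_impaired_range(c(70, 70, 65, 50, 25, 25, 25, 40))
detect_impaired_range <- function(thresholds, config = detection_config()) {
  validate_thresholds(thresholds)
  stopifnot(inherits(config, "detection_config"))
  qual <- !is.na(thresholds) & thresholds >= config$cutoff_db
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= config$min_run_length
  if (!any(keep)) return(NULL)
  # longest qualifying run; tie -> lowest start frequency
  cand <- which(keep)
  best <- cand[which.max(r$lengths[cand])]  # which.max returns first maximum
  structure(list(start = starts[best],
                 length = r$lengths[best],
                 freqs = freq_grid()[starts[best]:ends[best]]),
            class = "impaired_range")
}

#' @export
print.impaired_range <- function(x, ...) {
  cat(sprintf("Impaired range: %g-%g kHz (%d contiguous frequencies)\n",
              min(x$freqs), max(x$freqs), x$length))
  invisible(x)
}

#' Mean pure-tone threshold over a frequency range
#'
#' Arithmetic mean of the thresholds covered by an impaired range or by an
#' explicit frequency set. Every covered threshold must be present; a
#' missing threshold inside the range is an error, so that the caller (not
#' this function) decides how missing audiometry is handled.
#'
#' @param thresholds Numeric vector of 8 thresholds aligned to [freq_grid()].
#' @param range An `impaired_range` from [detect_impaired_range()], or `NULL`
#'   when `freqs` is given.
#' @param freqs Explicit frequencies (kHz) to average over, e.g.
#'   [traditional_band()]. Ignored when `range` is given.
#' @return Mean threshold in dB HL.
#' @export
#' @examples
#' mean_pta(c(70, 70, 65, 50, 25, 25, 25, 40),
#'          detect_impaired_range(c(70, 70, 65, 50, 25, 25, 25, 40)))
mean_pta <- function(thresholds, range = NULL, freqs = NULL) {
  validate_thresholds(thresholds)
  if (!is.null(range)) {
    stopifnot(inherits(range, "impaired_range"))
    idx <- range$start:(range$start + range$length - 1L)
  } else if (!is.null(freqs)) {
    idx <- match(freqs, freq_grid())
    if (anyNA(idx)) stop("`freqs` must be a subset of freq_grid()", call. = FALSE)
  } else {
    stop("supply either `range` or `freqs`", call. = FALSE)
  }
  vals <- thresholds[idx]
  if (anyNA(vals)) {
    stop("missing threshold inside the averaging range", call. = FALSE)
  }
  mean(vals)
}

#' Categorize a mean hearing threshold into a severity level
#'
#' Five-level severity grading of a mean threshold: below 40 dB is level 1
#' (mild), 40 to below 60 level 2 (moderate), 60 to below 80 level 3
#' (severe), 80 to below 100 level 4 (profound), and 100 dB or more level 5
#' (deaf). Bands are half-open `[lo, hi)`; the top band is `[100, Inf)`.
#'
#' @param mean_db Numeric vector of mean thresholds in dB HL; must be finite.
#' @return Integer vector of levels in 1..5, with a `labels` attribute.
#' @export
#' @examples
#' severity_category(c(35, 55, 75.63, 95, 100))
severity_category <- function(mean_db) {
  if (!is.numeric(mean_db) || any(!is.finite(mean_db))) {
    stop("`mean_db` must be finite numeric", call. = FALSE)
  }
  lev <- findInterval(mean_db, c(-Inf, 40, 60, 80, 100))
  structure(as.integer(lev),
            labels = c("mild", "moderate", "severe", "profound", "deaf"))
}

#' Severity level labels
#' @return Character vector naming levels 1 to 5.
#' @export
severity_labels <- function() c("mild", "moderate", "severe", "profound", "deaf")

#' Audiogram shape labels
#' @return Character vector of the five audiogram shape types.
#' @export
audiogram_shapes <- function() c("ascending", "u_shaped", "descending", "flat", "deaf")

#' Classify the shape of an audiogram
#'
#' Assigns exactly one of five conventional audiogram profiles from band
#' means: low band = mean over 0.125-0.5 kHz, mid band = 1-2 kHz, high
#' band = 3-8 kHz. The rules, applied in order, are: deaf when the overall
#' mean is 90 dB or more; flat when the spread between the best and worst
#' band is at most 10 dB; ascending when the low band is worse than the
#' high band by more than 10 dB (low-frequency loss); descending for the
#' mirror case; u-shaped when the mid band is worse than both edges by more
#' than 10 dB; otherwise flat.
#'
#' @param thresholds Numeric vector of 8 thresholds, no missing values.
#' @return A single string, one of [audiogram_shapes()].
#' @export
#' @examples
#' classify_audiogram_shape(c(70, 70, 65, 50, 25, 25, 25, 20))  # ascending
classify_audiogram_shape <- function(thresholds) {
  validate_thresholds(thresholds, allow_na = FALSE)
  low <- mean(thresholds[1:3])
  mid <- mean(thresholds[4:5])
  high <- mean(thresholds[6:8])
  tol <- 10
  if (mean(thresholds) >= 90) return("deaf")
  if (max(low, mid, high) - min(low, mid, high) <= tol) return("flat")
  if (low > high + tol && !(mid > low + tol)) return("ascending")
  if (high > low + tol && !(mid > high + tol)) return("descending")
  if (mid > low + tol && mid > high + tol) return("u_shaped")
  "flat"
}

#' Derive the audiometric features of one patient
#'
#' Computes the audiometric feature block from the four audiograms of a
#' patient (affected/unaffected ear at the initial visit and one month
#' post-treatment). The impaired range is detected on the initial
#' affected-ear audiogram and that same range is applied to both ears, so
#' the affected and unaffected averages always cover identical frequencies.
#'
#' @param aff_t0,una_t0 Initial-visit audiograms (affected, unaffected ear).
#' @param config A [detection_config()].
#' @return A list with `range` (the `impaired_range`), `pta_avg_affected`,
#'   `pta_avg_unaffected` (dB), `severity_affected`, `severity_unaffected`
#'   (levels 1-5), `run_length`, `shape` and the five 0/1 shape indicator
#'   values `shape_ascending` .. `shape_deaf`.
#' @export
derive_audiometric_features <- function(aff_t0, una_t0,
                                        config = detection_config()) {
  rng <- detect_impaired_range(aff_t0, config)
  if (is.null(rng)) {
    stop("no qualifying impaired range: patient does not meet the inclusion rule",
         call. = FALSE)
  }
  pta_aff <- mean_pta(aff_t0, rng)
  pta_una <- mean_pta(una_t0, rng)
  shape <- classify_audiogram_shape(aff_t0)
  flags <- as.integer(audiogram_shapes() == shape)
  names(flags) <- paste0("shape_", audiogram_shapes())
  c(list(range = rng,
         pta_avg_affected = pta_aff,
         pta_avg_unaffected = pta_una,
         severity_affected = as.integer(severity_category(pta_aff)),
         severity_unaffected = as.integer(severity_category(pta_una)),
         run_length = rng$length,
         shape = shape),
    as.list(flags))
}
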