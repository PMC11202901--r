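# Shared fixtures and independent oracles, all built in code.

# A patient whose two criteria variants contradict each other:
# low-frequency impairment (0.125-1 kHz) with an isolated impaired 8 kHz.
fixture_contradiction_patient <- function() {
  list(aff_t0 = c(70, 70, 65, 50, 25, 25, 25, 40),
       aff_t1 = c(60, 60, 45, 25, 15, 15, 15, 20))
}

# Exhaustive-enumeration oracle for the impaired-run selection rule:
# list every contiguous run of qualifying positions, keep those of
# sufficient length, select the longest (ties -> lowest start).
oracle_best_run <- function(qualifies, min_len) {
  best <- NULL
  n <- length(qualifies)
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (all(qualifies[s:e])) {
        len <- e - s + 1L
        if (len >= min_len && (is.null(best) || len > best$length)) {
          best <- list(start = s, length = len)
        }
      }
    }
  }
  best
}

# Exhaustive pairwise-concordance oracle for the AUROC (ties = 1/2).
oracle_auroc_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# A small calibrated cohort, generated once per test run and memoised.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(generator_config(n_patients = 200, seed = 404))
    }
    cache
  }
})
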