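# The 50-feature schema of the modelling dataset.

#' Schema of the modelling feature set
#'
#' The 50 features used for prognosis modelling, grouped into five
#' categories: demographic information, health records, laboratory
#' testing, onset and treatment, and pure-tone-audiometry summaries.
#' Hearing level enters only through the impaired-range averages of the
#' two ears, their severity categories, the run length and the audiogram
#' shape indicators -- never through per-frequency thresholds.
#'
#' @return A data.frame with columns `name`, `type` (`continuous`,
#'   `integer`, `binary` or `category`) and `category` (the variable group).
#' @export
feature_schema <- function() {
  f <- function(name, type, category) {
    data.frame(name = name, type = type, category = category,
               stringsAsFactors = FALSE)
  }
  rbind(
    f("age", "integer", "demographic"),
    f("height", "continuous", "demographic"),
    f("weight", "continuous", "demographic"),
    f("gender_female", "binary", "demographic"),
    f("bmi", "continuous", "health"),
    f("smoking_pack_years", "continuous", "health"),
    f("sbp", "integer", "health"),
    f("dbp", "integer", "health"),
    f("smoking", "binary", "health"),
    f("smoking_post_cessation", "binary", "health"),
    f("hypertension", "binary", "health"),
    f("diabetes", "binary", "health"),
    f("stroke", "binary", "health"),
    f("dizziness", "binary", "health"),
    f("tinnitus", "binary", "health"),
    f("hyperlipidemia", "binary", "health"),
    f("ckd", "binary", "health"),
    f("mi_angina", "binary", "health"),
    f("total_cholesterol", "continuous", "laboratory"),
    f("ldl", "continuous", "laboratory"),
    f("triacylglycerol", "continuous", "laboratory"),
    f("hemoglobin", "continuous", "laboratory"),
    f("bun", "continuous", "laboratory"),
    f("creatinine", "continuous", "laboratory"),
    f("wbc", "continuous", "laboratory"),
    f("neutrophil_pct", "continuous", "laboratory"),
    f("lymphocyte_pct", "continuous", "laboratory"),
    f("nlr", "continuous", "laboratory"),
    f("platelet", "continuous", "laboratory"),
    f("pt_sec", "continuous", "laboratory"),
    f("aptt_sec", "continuous", "laboratory"),
    f("onset_to_treatment_days", "integer", "onset_treatment"),
    f("onset_to_itdi_days", "integer", "onset_treatment"),
    f("hospitalization", "binary", "onset_treatment"),
    f("affected_side_left", "binary", "onset_treatment"),
    f("itdi_duration_category", "category", "onset_treatment"),
    f("onset_month", "category", "onset_treatment"),
    f("run_length", "category", "onset_treatment"),
    f("tx_systemic", "binary", "onset_treatment"),
    f("tx_itdi", "binary", "onset_treatment"),
    f("tx_combined", "binary", "onset_treatment"),
    f("pta_avg_affected", "continuous", "pta"),
    f("pta_avg_unaffected", "continuous", "pta"),
    f("severity_affected", "category", "pta"),
    f("severity_unaffected", "category", "pta"),
    f("shape_ascending", "binary", "pta"),
    f("shape_u_shaped", "binary", "pta"),
    f("shape_descending", "binary", "pta"),
    f("shape_flat", "binary", "pta"),
    f("shape_deaf", "binary", "pta")
  )
}

# Features that are rounded to integers after imputation (integer, binary
# and ordered-category encodings).
integer_feature_names <- function() {
  s <- feature_schema()
  s$name[s$type %in% c("integer", "binary", "category")]
}

binary_feature_names <- function() {
  s <- feature_schema()
  s$name[s$type == "binary"]
}
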