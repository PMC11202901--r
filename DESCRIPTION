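Package: ppsc
Title: Patient-Personalized Siegel Criteria for Sudden Hearing Loss Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing recovery from idiopathic sudden sensorineural
    hearing loss with Siegel's criteria applied over each patient's own
    impaired frequency range instead of a fixed band. Detects the contiguous
    run of impaired audiometric frequencies, grades recovery under both the
    traditional and the patient-personalized criteria, compares the two
    assessments, and runs a full prognosis-modelling pipeline: chained-
    equations imputation, min-max scaling, repeated stratified cross-
    validation over a tuned eight-model zoo with a soft-voting ensemble, and
    Shapley-value attribution of the best model. A seeded synthetic-cohort
    generator calibrated to published recovered versus non-recovered
    contrasts drives every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    rpart,
    e1071,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
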