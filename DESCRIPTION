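Package: uteroflow
Title: Personalised Maternal Haemodynamic Models and Utero-Ovarian
    Biomarkers for Pre-Eclampsia Screening
Version: 0.1.0
Authors@R:
    person("BEST", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reduced model of the maternal arterial circulation
    (one-dimensional pulse-wave propagation in the larger arteries with
    lumped-parameter terminal beds and a utero-ovarian resistance-compliance
    cascade), together with a per-patient calibration loop that converges the
    model to non-invasive measurements (systolic/diastolic pressure, heart
    rate, cardiac output, pulse wave velocity, uterine Doppler velocities).
    From the calibrated "digital twin" the package computes dimensionless
    haemodynamic biomarkers (Buckingham-Pi terms, pressure pulsatility index,
    resistance and pulsatility indices at arcuate and radial/spiral sites) and
    evaluates them as binary classifiers of early-onset pre-eclampsia with
    t-tests, effect sizes, logistic regression, one-dimensional k-means, ROC
    AUC, DeLong comparisons and a power/sample-size calculator.  A synthetic
    cohort generator emulating published group statistics makes the whole
    pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
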