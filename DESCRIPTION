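Package: empredict
Title: Sperm Membrane Potential Calibration and IVF Outcome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Determines absolute sperm plasma-membrane potential (Em, mV)
    from cuvette fluorimetry traces of the potentiometric dye DiSC3(5) by
    Nernst-based internal calibration with valinomycin and sequential KCl
    additions. Classifies capacitation-associated Em behaviour
    (hyperpolarizing, depolarizing, unchanged), hyperactivated motility from
    CASA kinematics, and acrosomal responsiveness, and evaluates capacitated
    sperm Em as a predictor of in vitro fertilization success by empirical
    ROC analysis with Hanley-McNeil standard errors and Youden-optimal
    cutoffs. A seeded synthetic-data module generates dye traces and
    donor/patient cohorts so the complete pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
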