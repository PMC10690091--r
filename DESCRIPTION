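Package: serdpd
Title: Pharmacokinetic/Pharmacodynamic Exposure, Estrogen Receptor
    Degradation Kinetics and Tumor Growth Inhibition Analytics for
    Preclinical SERD Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative backbone for preclinical studies of selective
    estrogen receptor (ER) degraders: one-compartment oral
    pharmacokinetics with repeat-dose superposition and free-fraction
    correction; an indirect-response (stimulation-of-loss) model of ER
    protein turnover with half-life estimation, in vivo degradation-IC50
    fitting and average suppression over a dosing interval; exponential
    tumor-growth modelling with per-animal growth-rate fits, percent
    tumor-volume change, geometric-mean tumor growth inhibition and
    one-tailed unequal-variance tests on log volume change;
    proliferation-assay normalization with four-parameter-logistic
    IC50/pIC50 fitting; z-score gene-signature scoring with ANCOVA group
    comparison; and a seeded synthetic-study generator with known ground
    truth so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
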