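Package: ceqpbpk
Title: Population Physiologically Based Pharmacokinetics of Cefquinome in Swine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A six-compartment physiologically based pharmacokinetic (PBPK) model
    of intramuscular cefquinome in nursery pigs with a permeability-limited lung
    (blood, interstitial-fluid and tissue sub-compartments) and a two-step
    intramuscular depot. Provides microdialysis probe-calibration arithmetic and
    non-compartmental analysis, calibration and validation metrics, local
    sensitivity analysis (normalized sensitivity coefficients), Monte Carlo
    population simulation from truncated parameter distributions, percent time
    above MIC dosage evaluation with probability of target attainment, and
    withdrawal-interval estimation of liver and kidney residues against maximum
    residue limits. Includes a synthetic-data generator emulating the study
    designs the model is calibrated against.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
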