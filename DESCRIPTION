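Package: cnspk
Title: Semi-Physiological Pharmacokinetics of Ondansetron CNS Disposition
    Under P-glycoprotein Efflux Modulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Five-compartment linear pharmacokinetic model of ondansetron
    disposition in rat plasma, brain, spinal cord and cerebrospinal fluid
    with first-order P-glycoprotein efflux at the blood-brain barrier.
    Includes an exact linear-system simulator with a stiff ODE backend,
    naive-pooled maximum-likelihood estimation with proportional residual
    error across wild-type, Pgp-knockout and tariquidar-co-dosed groups,
    noncompartmental analysis (AUC, terminal slope, mean residence time,
    clearance, steady-state volume, tissue partition coefficients), forward
    simulation scans over the extent of Pgp inhibition, and a study-design
    faithful synthetic data generator with proportional noise and
    detection-limit censoring.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
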