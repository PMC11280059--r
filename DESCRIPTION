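Package: vildapbpk
Title: Whole-Body Physiologically Based Pharmacokinetics of Vildagliptin in Health and Chronic Kidney Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A whole-body physiologically based pharmacokinetic (PBPK) model of
    the DPP-4 inhibitor vildagliptin for healthy adults and patients with
    moderate or severe chronic kidney disease (CKD). Builds virtual individuals
    and populations from an embedded reference anatomy, computes Poulin-Theil
    tissue:plasma partition coefficients from tissue composition, integrates a
    perfusion-limited organ model with Weibull dissolution, gastric emptying
    and intestinal-transit absorption, and renal filtration plus
    kidney-localized Michaelis-Menten hydrolysis scaled by glomerular
    filtration rate. Includes non-compartmental analysis (Cmax, AUC, lambda-z,
    clearance), model-qualification statistics (predicted/observed ratios,
    average fold error, visual predictive checks, two-fold acceptance), and a
    bisection search for CKD dose adjustment matching healthy drug exposure.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
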