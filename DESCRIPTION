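Package: hepapk
Title: Liver-Centric Multiscale Pharmacokinetics of Acetaminophen
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates whole-body disposition and hepatic metabolism of
    acetaminophen (APAP) and its glucuronide and sulfate conjugates across
    three coupled biological scales: a physiologically based pharmacokinetic
    (PBPK) compartment model of the whole body, a deterministic parcel model
    of blood flow and solute exchange in a representative liver sinusoid
    lined with zonated hepatocytes, and a Michaelis-Menten reaction network
    for Phase I/II metabolism and glutathione turnover inside each
    hepatocyte. Includes local parameter sensitivity analysis with pairwise
    interaction coefficients, virtual-population simulation with
    truncated-normal parameter multipliers, ADME curve metrics (Cmax, Tmax,
    AUC, RMSE against reference data), synthetic reference generation, SBML
    export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
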