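Package: ontopbpk
Title: Population-PBPK Estimation of Enzyme Ontogeny from Sparse Pediatric
    Pharmacokinetic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reduced ("population") physiologically based pharmacokinetic
    modelling for the estimation of drug-metabolising-enzyme and transporter
    ontogeny functions from sparse paediatric and adult concentration data.
    Provides a registry of structural ontogeny model families (sigmoid Emax,
    Gompertz, declining and bell-shaped combinations), age-dependent hepatic
    physiology (liver weight, microsomal protein, blood flow, glomerular
    filtration maturation), a well-stirred-liver structural PK model with
    pathway-partitioned intrinsic clearance, a Laplace-approximation
    nonlinear mixed-effects engine, model qualification tools (bootstrap,
    goodness of fit, visual predictive checks, post hoc clearance-age scans,
    multi-family ontogeny scans), a sparse-trial simulator, and static
    extrapolation utilities (neonate exposure, fraction-metabolised versus
    age, CYP3A drug-drug-interaction AUC ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
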