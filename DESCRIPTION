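Package: shiftnav
Title: Navigator-Guided Chemical Shift and Concentration Prediction for Urine 1H NMR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains spline-based models that map the composition of a urine-like
    mixture (metabolite and inorganic-ion concentrations, pH, temperature) to the
    1H NMR chemical shifts of its metabolite signals, and back. Prediction in an
    unknown spectrum is bootstrapped from five "navigator" signals (two citrate
    doublets of doublets, two creatinine singlets, one glycine singlet) detected
    by peak picking and multiplet criteria; a reduced route (navigator shifts
    only) and a full route (all active-signal shifts) are combined into final
    shift and concentration estimates with rRMSE-derived uncertainties. Includes
    a multivariate adaptive regression splines (MARS) engine with GCV pruning and
    ANOVA variable importance, and a synthetic artificial-urine generator
    (fast-exchange shift responses, Lorentzian multiplet spectra) that makes the
    whole pipeline trainable and testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
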