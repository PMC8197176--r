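Package: actdyn
Title: Tumour and CTL Population Dynamics After Adoptive Cell Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary differential equation model of a murine melanoma attacked
    by adoptively transferred cytotoxic T lymphocytes (CTLs), with an
    observation layer that converts tumour-volume series and intravital
    two-photon count records into per-day process rates, maximum-likelihood
    Poisson models for CTL killing with AIC/BIC comparison, an RMSE objective
    fitted by local-to-best differential evolution, a synthetic-cohort
    generator emulating the study design, and scenario sweeps that attribute
    tumour control to cytotoxic versus antiproliferative CTL effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    withr
Config/testthat/edition: 3
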