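Package: cvrtime
Title: Temporal-Feature Analysis of BOLD Cerebrovascular Reactivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Model-free analysis of BOLD-fMRI cerebrovascular reactivity
    (CVR) experiments using boxcar hypercapnia gas challenges. Estimates
    per-challenge CVR with the Theil-Sen (Sen's slope) non-parametric
    estimator normalized by the end-tidal CO2 change, quantifies the
    hypercapnia-to-normocapnia transition rate by linear regression, and
    provides a conventional gamma-HRF general-linear-model comparator with
    AIC-based model comparison. Includes a simulator for fast (sigmoidal)
    and slow (ramp) hypercapnic responses across temporal-SNR levels, a
    synthetic two-challenge cohort generator, and group-level regression
    models linking the transition rate to the subsequent CVR response.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
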