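Package: specsel
Title: Wavelength Selection and Partial Least Squares Calibration for
    Vibrational Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Multivariate calibration of portable near-infrared and Raman
    spectra against a continuous reference property such as the iodine value
    of edible oils. Implements PLS1 regression with k-fold cross-validation
    for latent-variable selection, Kennard-Stone calibration/test
    partitioning, and four resampling-based wavelength selection algorithms:
    Monte Carlo uninformative variable elimination (MCUVE), competitive
    adaptive reweighted sampling (CARS), bootstrapping soft shrinkage (BOSS)
    and variable combination population analysis (VCPA). A synthetic
    oil-blend spectrum generator with known informative channels supports
    method validation, and a repeated-evaluation benchmark summarises
    selection quality and prediction error across stochastic repeats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
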