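Package: nirspa
Title: Variable-Selection Diagnostics for Near-Infrared Tissue Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometric classification workflow for near-infrared (NIR)
    diffuse-reflectance spectra of tissue: synthetic two-class spectrum
    simulation, standard normal variate (SNV) and Savitzky-Golay derivative
    preprocessing, principal component exploration, variable selection by the
    successive projections algorithm coupled with pooled-covariance
    Mahalanobis linear discriminant analysis (SPA-LDA), a full-spectrum
    PLS-DA baseline with cross-validated latent-variable selection, and
    sensitivity/specificity evaluation across training, validation and test
    subsets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
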