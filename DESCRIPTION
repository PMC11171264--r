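Package: melbands
Title: Spatial Band Morphometry and Prognostic Modelling for Multiplex
    IHC Melanoma Slides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying spatial and morphological features of
    melanoma from multiplex immunohistochemistry (mIHC) cell detection
    tables. Implements per-slide two-phase marker gating (Otsu split of
    the intensity distribution followed by a two-component Bayesian
    Gaussian mixture on the log foreground, thresholding at the weighted
    density intersection), PCA-based tumor orientation and estimated
    thickness, distance-transform partition of the tumor into
    superficial, middle and invasive bands, per-band cell densities and
    nuclear morphometry, and Cox proportional-hazards evaluation with
    Harrell's concordance, bootstrap confidence intervals and
    leave-one-out cross-validation. A synthetic slide and cohort
    generator with retained latent truth supports end-to-end testing
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    survival,
    mgcv,
    pracma,
    EBImage,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
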