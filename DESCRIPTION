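Package: mboss
Title: Multivariate Bag-of-SFA-Symbols Classification of Wearable Sensor Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Symbolic classification of multivariate sensor time series for
    human activity recognition. Windows of each axis are approximated by
    truncated Fourier coefficients, quantized into short words by equi-depth
    Multiple Coefficient Binning, aggregated into numerosity-reduced word
    histograms, fused across axes, and classified against per-class tf-idf
    vectors by cosine similarity. Includes grid-search model fitting with
    stratified cross-validation, personalized and leave-one-subject-out
    evaluation protocols, hand-crafted time/frequency baseline features, a
    seeded synthetic activity-signal generator, CSV/JSON input-output, and
    memory-footprint accounting.
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
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
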