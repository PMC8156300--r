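Package: ripasync
Title: Thoracoabdominal Asynchrony Assessment from Respiratory Inductance
    Plethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes respiratory indices from dual-band respiratory
    inductance plethysmography recordings: the FFT cross-spectral phase
    difference between rib-cage and abdominal excursions, the percentage
    rib-cage contribution, the labored breathing index, and the respiratory
    rate. Summarises the phase series as an inverse cumulative percentage
    (survival) curve with median and quartile markers, classifies breathing
    as normal or abnormal with a cross-validated elastic-net logistic model
    on the curve values, and assembles per-subject flag reports that combine
    index deviations from healthy reference values with vital-sign range
    checks. Includes a seeded generator of synthetic two-band breathing
    signals for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
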