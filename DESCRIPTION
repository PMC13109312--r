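Package: kernelrows
Title: Kernel Row Detection and Phenotyping for Maize Ears from 2-D Kernel Coordinates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects kernel rows on a single maize (corn) ear from the 2-D kernel
    centre coordinates emitted by any kernel localizer, and derives the three
    quantity traits kernels per ear, rows per ear (visible side) and kernels per
    row. Rows are found by squeezed K-means clustering of the reliable middle
    segment of the pose-normalized ear, with the row count selected by the mean
    silhouette coefficient, then extended to both ear ends by a greedy angular
    search with three position-correction regimes; partial rows at the ear
    boundaries are recovered by a second squeezed clustering. Ships a synthetic
    ear generator with ground-truth row labels (spiral and linear arrangements,
    taper, jitter, dropout), the standard count and assignment evaluation
    metrics, the inter-kernel angle statistic, and a hyperparameter sensitivity
    sweep, plus broom-style tidiers and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
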