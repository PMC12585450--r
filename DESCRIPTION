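Package: coordgait
Title: Intersegmental Coordination Analysis for Running Gait via Modified
    Vector Coding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to quantify hip-ankle and knee-ankle coordination during
    running from sagittal-plane joint-angle time series and a synchronized
    vertical ground reaction force channel. Implements zero-phase Butterworth
    filtering, quintic gap filling, force-threshold gait event detection,
    stride segmentation with 101-point time normalization, modified
    vector-coding coupling angles, circular statistics (mean resultant length
    and circular standard deviation) for coordination variability, subphase
    aggregation with coordination-pattern classification, and mixed 2x2
    (group x time) ANOVA with partial eta-squared and noncentral-F confidence
    intervals. A synthetic running-gait generator with known ground-truth
    coupling supports testing without motion-capture data.
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
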