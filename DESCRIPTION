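Package: sleepfbn
Title: Functional Brain Network Analysis of Sleep EEG with Clinical Trial
    Endpoint Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline from multichannel sleep EEG to
    Pearson-correlation functional brain networks and their graph-theoretic
    summaries (degree, clustering coefficient, characteristic path length,
    global efficiency, and spectral graph energy), together with the
    statistical comparison plan of a two-arm longitudinal trial
    (independent, paired, repeated-measures, and categorical contrasts) and
    a regional gray-matter volume analysis. Includes seeded synthetic-data
    generators for coupled NREM-II-like EEG, two-arm clinical-scale tables,
    and paired regional volume tables, so every stage is testable with
    known ground truth; a minimal EDF reader/writer; and ggplot2 graphics
    for networks and metric trajectories.
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
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
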