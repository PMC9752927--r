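Package: pligraph
Title: Phase-Lag-Index Brain Network Analysis for Interictal Scalp EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Functional brain-network analysis of resting-state scalp EEG on
    the 25-channel IFCN montage. Estimates phase lag index (PLI) connectivity
    per frequency band from Hilbert instantaneous phases, builds weighted
    networks on 1/PLI edge distances, and summarizes them with small-world
    metrics (clustering coefficient, characteristic path length), minimum
    spanning tree metrics (diameter, leaf fraction, betweenness centrality,
    tree hierarchy, kappa), modularity and participation coefficients, and
    spectral indices (mean frequency, frontal laterality index). Includes a
    seeded synthetic coupled-oscillator EEG cohort generator with a
    severity-linked frontotemporal theta coupling, and a cohort statistics
    stage (ANOVA with Tukey post-hoc, Spearman severity correlations, and
    stepwise multiple linear regression of severity scores).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
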