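Package: msfme
Title: Multiscale Fuzzy Measure Entropy Analysis of EEG and ECG Recovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nonlinear recovery analysis of synchronized EEG and ECG
    recordings via multiscale fuzzy measure entropy (MSFME). Provides a
    fast fuzzy measure entropy kernel with coarse-graining over scale
    factors, a session pipeline turning cleaned multichannel recordings
    into per-minute baseline-normalized entropy trajectories aggregated
    over cerebral lobes, a heterogeneity-based scale selection procedure,
    nonparametric time and condition statistics (Wilcoxon signed-rank z
    with a rank-biserial Cohen's d chain, Kruskal-Wallis with Bonferroni
    post hoc), Spearman brain-heart entropy coupling, and a seeded
    synthetic-study generator with EDF and CSV writers so the full
    pipeline is testable end to end without access to recorded subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    signal,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
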