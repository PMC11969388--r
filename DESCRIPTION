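Package: antdol
Title: Division of Labour in Ant Colony Defence
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies division of labour (DOL) in colony defence from
    automated-tracking trajectories and manually annotated behavioural
    events, as studied in clonal raider ant (Ooceraea biroi) colonies.
    Provides a synthetic-colony simulator built on heterogeneous response
    thresholds and a two-state movement model; trajectory preprocessing
    (aberrant-position detection, gap interpolation); baseline exploration
    and activity metrics (occupancy-grid Shannon entropy, proportion of
    time active, mean active-bout duration); a per-ant defence score
    combining sting counts and durations normalised by encounter number;
    DOL statistics (rank consistency across trials with Benjamini-Hochberg
    correction, within-colony behavioural variation); a subsampling null
    for group-size effects on variation; and an end-to-end pipeline with a
    reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml,
    zoo
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
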