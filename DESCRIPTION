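Package: popchange
Title: Two-Stage Analysis of Vertebrate Population Trends and Fluctuations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying population change from abundance time
    series in the style of the Living Planet Database. Stage one fits a
    state-space (random walk with drift) model per population that
    partitions variance into process noise and observation error and
    classifies each trend by its 95% confidence interval. Stage two models
    the per-population estimates across realms, biomes, taxa, latitude,
    rarity metrics, IUCN Red List Categories and threats with Bayesian
    Gaussian mixed models (blocked Gibbs sampling, species random
    intercepts, optional known measurement-error variances), and assesses
    phylogenetic signal with tree-structured random effects repeated over
    tree samples. Also included: rarity metrics (geodesic convex-hull
    geographic range from cleaned occurrence records, mean population
    size, habitat specificity), a randomization null for trend
    significance, truncation sensitivity checks, Hartigan's dip test for
    bimodality, and a synthetic-data generator that provides ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    geosphere,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
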