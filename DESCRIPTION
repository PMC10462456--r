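Package: duckweedyeast
Title: Culture-Based Survey Analysis of Duckweed-Associated Yeasts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for culture-dependent microbial isolate surveys,
    built around a 252-strain inventory of yeasts isolated from duckweed
    (Lemnaceae) in Thailand. Provides a validated tabular data model for
    per-isolate records with tri-state plate-assay measurements,
    sequence-identity threshold rules for species- and genus-level rank
    assignment, alpha-diversity and frequency statistics (Shannon-Wiener,
    Shannon equitability, unbiased Simpson, relative frequency, frequency of
    occurrence), nonparametric species-richness estimators (Chao1, first-order
    jackknife, analytic bootstrap) with sample-based accumulation curves,
    Jaccard distances with principal coordinate analysis, plant-growth-
    promotion trait summaries (IAA, siderophore activity units, phosphate
    solubilization efficiency), and a seeded synthetic-survey generator for
    benchmarking estimator behaviour against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
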