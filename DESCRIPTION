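Package: genophen
Title: Genotype-Metabolome Distance Correlation for Yeast Marker Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Correlates per-locus DNA distance matrices with FTIR and LC-MS
    metabolomic distance matrices for closely related yeast strains, both on
    whole profiles and per spectral descriptor, across ethanol stress
    conditions. Implements Mantel-style matrix correlation with exhaustive
    or sampled permutation tests, the percentage-of-significative-wavelengths
    (PSW) statistic and its trend typology, FTIR preprocessing (rubberband
    baseline correction, vector normalization, region extraction),
    metabolomics feature-table processing (IQR filtering, median
    normalization, Pareto scaling), PLS-DA with VIP-based metabolite
    selection, evolutionary distances (p, JC69, K80, TN93) with
    neighbor-joining trees and bootstrap support, and a synthetic-data
    generator that emulates the full study design (marker alignments evolved
    on a tree, spectra with planted condition-dependent signals, feature
    tables, viability counts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
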