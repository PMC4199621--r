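Package: h4screen
Title: Sequential Ligand- and Structure-Based Screening for hH4R Antagonists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for indexing chemicals for human
    histamine H4 receptor (hH4R) antagonism. Learns descriptor-range filters
    from labelled actives and decoys by Iterative Stochastic Elimination with
    the Matthews correlation coefficient as objective, combines the resulting
    ensemble of efficient filters into a Molecular Bioactivity Index for
    ranking screening libraries, and triages docked poses by electrostatic
    energy clustering (exact one-dimensional k-means) plus carboxylate-contact
    distance scoring against the D3.32/E5.46 binding-site residues. Includes
    enrichment-factor evaluation with random sub-sampling, consensus-library
    selection, drug- and lead-likeness rule filters, ECFP4-style circular
    fingerprints with Tanimoto diversity filtering, and a synthetic-data
    module that generates labelled descriptor sets with planted range rules
    and docking-pose populations with planted binders.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
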