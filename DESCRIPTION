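Package: ratmind
Title: Morphometric Inverse Divergence Similarity Networks for the Rat Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construct region-balanced structural similarity networks (MIND:
    Morphometric Inverse Divergence) from voxel-level magnetization transfer
    ratio tables, characterize their weighted topology (nodal strength, hubs,
    rich club) against distance-preserving null ensembles, validate them
    against spatial distance, cortical-type, tract-tracing and gene-expression
    references, and model developmental, aging and early-life-stress effects
    with linear mixed models and permutation inference. A synthetic-cohort
    generator with planted ground truth makes every stage testable without
    MRI data.
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
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
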