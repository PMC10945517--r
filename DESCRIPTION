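Package: seedlingqtl
Title: Bulk-Segregant QTL Scanning and Drought-Context Analyses for Early
    Root Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping quantitative trait loci for early primary
    root growth in pearl millet from bulk-segregant sequencing, and for
    placing them in their drought-stress context. Implements the
    Euclidean-distance allele-frequency statistic with fourth-power
    windowed smoothing and a simulation-based significance threshold, the
    variant filtering cascade that feeds it, broad-sense heritability from
    line-replicated phenotypes, root-tip growth kinematics from logistic
    cell-length profiles, and classification of seasonal soil-water
    trajectories into stress patterns by dynamic-time-warping clustering.
    A synthetic-data module simulates every input (F2 crosses, pooled
    bulk sequencing, phenotype panels, cell-length profiles, rainfall and
    a soil-water bucket) so the full pipeline is testable without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    emmeans,
    jsonlite,
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
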