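Package: spotclone
Title: Spatial Mapping of Genetic Clones in Spot-Based Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intra-tumour heterogeneity in spot-based
    spatial transcriptomics (Visium-style hexagonal lattices). Implements a
    Potts-smoothed k-means segmentation (iterated conditional modes) for
    spatially coherent tissue regions, a spot-normalised spatial
    heterogeneity index, transcriptome-based mapping of genetic clones from
    copy-number-informative gene sets with a non-spatial control clustering,
    alpha-shape clone territories with nucleus-to-clone assignment and
    nuclear-morphology statistics, FISH-style per-nucleus count validation,
    Moran's I ranking of spatially variable genes, hypergeometric signature
    enrichment, and rule-based tumour-microtube quantification. A synthetic
    data generator emulates the assumed statistical structure (hexagonal
    lattices, clone copy-number dosage effects on negative-binomial counts,
    normal-cell contamination, clone-dependent nuclear areas, probe counts)
    so the full pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    deldir,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    sp,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
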