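Package: dualvirome
Title: Dual-Source (Bulk + VLP) Metagenomic Profiling of Gut Bacterial and
    Viral Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to reconstruct and compare gut bacterial and viral
    populations from paired whole-microbial ("bulk") and viral-like-particle
    (VLP) metagenomes. Implements viral genome validation and
    temperate/virulent lifestyle classification from gene annotations,
    breadth-of-coverage presence calling and abundance profiling,
    sequencing-depth saturation analysis, community statistics (alpha
    diversity, Bray-Curtis, PCoA, PERMANOVA, Procrustes), and a three-engine
    consensus differential-abundance procedure. Ships a synthetic community
    generator that emulates paired bulk/VLP mouse-gut study designs so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    car,
    Biostrings,
    optparse,
    withr
Config/testthat/edition: 3
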