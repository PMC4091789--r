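Package: tilechip
Title: Bound-Region Calling, Motif Scoring and State Comparison for
    Tiling-Array ChIP-chip
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for mapping sequence-specific DNA-binding
    proteins (PHO/PHOL/SFMBT and the human ortholog YY1) from tiling-array
    ChIP-chip data. Turns replicate probe intensities into smoothed
    ChIP/Input ratio profiles (trimmed mean over a sliding window), calls
    bound regions with a background-adjustment / gap-clustering /
    minimum-length procedure, locates 6-feature binding peaks and ranks
    sites by binding strength, computes overlap-versus-strength curves
    against reference interval sets (Polycomb response elements, TSS
    windows), scores site sequences with a position weight matrix scanned
    on both strands and counts conserved GCCAT core motifs, and compares
    per-PRE adjusted binding signals between repressed and active chromatin
    states with exact Wilcoxon signed-rank tests. Ships a seeded synthetic
    ChIP-chip simulator so the whole pipeline is testable without array
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
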