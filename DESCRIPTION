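Package: riboclean
Title: Ribosome Profiling Library QC, rRNA Contaminant Discovery, and
    Depletion Oligo Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing plant ribosome profiling (Ribo-seq)
    libraries. Accounts for library composition across genomic features and
    rRNA species, discovers the recurrent high-coverage rRNA contaminant
    fragments that dominate undepleted libraries and designs biotinylated
    depletion-oligo cocktails with abundance-matched molar ratios,
    calibrates P-site offsets separately for cytosolic 80S (5'-anchored)
    and chloroplast 70S (3'-anchored) ribosomes, computes triplet
    periodicity, metagene, size-distribution and cross-library count QC,
    and maps contaminant fragments onto a ribosome structure to score
    protein shielding and predict nuclease-accessible fragments in silico.
    Includes a seeded synthetic-data generator (toy genomes, rRNA
    references, footprint libraries with truth tables) so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
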