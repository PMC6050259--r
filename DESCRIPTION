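Package: phagoscope
Title: Shotgun-Metagenome Phagobiota Profiling and Phage-Host Ratio Analysis
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies bacteriophage communities from shotgun metagenome
    reads and assembled contigs by alignment against a phage genome
    database, profiles bacterial taxa from clade-specific marker genes,
    computes alpha- and beta-diversity statistics (ACE, Chao1, Shannon,
    Simpson, Bray-Curtis, Spearman dissimilarity, PCoA, PERMANOVA), and
    derives the phage/bacteria ratio ("lytic potential") with
    lytic-versus-temperate lifestyle comparisons. Includes a synthetic
    two-group cohort simulator with known ground truth (genomes, prophage
    integration, reads, contigs) for end-to-end validation of the
    pipeline's parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    yaml,
    withr,
    Biostrings,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    Rsamtools,
    optparse,
    jsonlite
Config/testthat/edition: 3
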