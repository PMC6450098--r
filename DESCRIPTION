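Package: ncldvtools
Title: Comparative Genomics of Giant Viruses and Their Amoeba Hosts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the comparative-genomic analyses
    used to characterise a newly isolated nucleocytoplasmic large DNA virus
    (NCLDV) and its interactions with its Acanthamoeba host: reciprocal
    best-hit detection of lateral gene transfer (LGT) candidates with
    exclusion-based direction inference, RPKM expression comparison of
    transferred versus vertically inherited genes, genome composition
    statistics (G+C content and windowed track, coding density, basic-residue
    proportions, closest-homolog taxonomy tallies), gene-content
    neighbor-joining cladistics with bootstrap support, virion-proteome
    emPAI abundance ranking with in-silico tryptic digestion, and icosahedral
    capsid lattice geometry. A synthetic-data module generates every input
    with known ground truth so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    ape,
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
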