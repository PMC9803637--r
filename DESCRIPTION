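Package: tnrtools
Title: Trinucleotide-Repeat RNA Analysis: Repeat Reads, Gene Catalogs,
    Enrichment, RISC Profiles and Hairpin Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying expanded CAG-family trinucleotide repeats
    (TNRs) in RNA and their RNA-interference consequences. Detects maximal
    repeat tracts in sequences and classifies small RNA-seq reads by their
    longest tract; builds nested catalogs of repeat-containing genes from
    stitched transcript regions (GMT output); runs preranked gene-set
    enrichment with a weighted Kolmogorov-Smirnov statistic and a gene-label
    permutation null; profiles RISC-bound (Argonaute pulldown) small RNA
    libraries into CAG-phase, CCG-phase and other read groups with length
    and species tables; and quantifies hairpin stability and uninterrupted
    CAG stem length for huntingtin and androgen-receptor repeat variants by
    delegating minimum-free-energy folding to ViennaRNA's RNAfold. A seeded
    synthetic-data generator produces planted-truth fixtures for every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    fgsea,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: ViennaRNA (RNAfold on the PATH) for hairpin folding
Config/testthat/edition: 3
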