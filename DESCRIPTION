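Package: normcov
Title: Chromosome-Normalized Replicon Coverage and Plasmid Stability
    Inference for Multi-Replicon Bacterial Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying replicon copy number and plasmid inheritance
    in bacteria with multipartite genomes. Simulates cell populations with a
    chromosome ploidy and per-plasmid copy numbers and carriage fractions,
    generates paired-end sequencing reads with truth alignments, computes
    windowed read depth and the NormCov statistic (per-window depth divided
    by the chromosome mean depth), estimates replicon copy number with
    bootstrap intervals, discriminates chromosome polyploidy from unstable
    plasmid inheritance with an exact binomial colony-panel test, and screens
    within-culture sequence heterogeneity with a pileup allele-fraction
    cutoff. Includes GC and GC-skew replicon tracks and a registry of the
    Aminobacter sp. MSH1 replicons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
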