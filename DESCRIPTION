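Package: bisulfitr
Title: Spike-In Controlled Bisulfite Sequencing Simulation and Methylation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable reimplementation of a spike-in
    controlled whole-genome bisulfite sequencing (WGBS) workflow and a tRNA
    m5C amplicon bisulfite workflow. Includes a synthetic-data generator that
    emulates a three-genome spike-in design (a large unmethylated genome, an
    unmethylated lambda-like negative control, a CpG-methylated human-like
    positive control), quality- and length-trimming of reads, a bisulfite-aware
    three-letter paired-end aligner with uniqueness and proper-pair filters,
    per-cytosine non-conversion ratio pileup with CpG/CHG/CHH context
    annotation, methylome summary statistics (ratio-bin histograms, tail
    fractions, dinucleotide context tables, spike-in conversion rate, mean CpG
    coverage, conversion-corrected global methylation level), and a per-read by
    per-site tRNA methylation matrix builder for cytosine-38 amplicon data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
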