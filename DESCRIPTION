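Package: circtarget
Title: Targeted Sequencing Library Design and Evaluation by Genomic DNA
    Circularization
Version: 0.1.0
Authors@R:
    person("circtarget", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Design and in-silico evaluation of targeted-circularization
    sequencing assays. Provides in-silico restriction digestion of a
    reference genome, enumeration and quality filtering of splint capture
    oligonucleotides under anchoring, SNP-avoidance, circle-size and
    arm-G+C constraints, full oligo and vector sequence assembly with
    uracil substitution, a seeded synthetic capture/read simulator with a
    size- and G+C-dependent yield model and PCR amplification skew, and
    capture-performance analytics from alignments: on-target fragment-end
    tagging, coverage thresholds, median-normalized uniformity curves,
    performance classification and size/G+C yield correlates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
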