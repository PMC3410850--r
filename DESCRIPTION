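Package: rhizopopgen
Title: Population Genomics of Paired Bacterial Species with Multi-Replicon Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genomic analysis of haploid bacterial strain
    panels sampled from two closely related species with multi-replicon genomes
    (a chromosome plus megaplasmids), such as Sinorhizobium meliloti and
    S. medicae. Implements read-count consensus calling with depth and
    agreement thresholds, per-gene and sliding-window nucleotide diversity
    statistics (theta-pi, Watterson's theta, Tajima's D, Fay and Wu's H,
    synonymous/nonsynonymous partition), detection of interspecific horizontal
    gene transfer from the ratio of shared polymorphisms to fixed differences
    with clustering of transferred genes into contiguous regions, joint
    D-H empirical-tail scans for recent selective sweeps, neighbor-joining
    genealogies under the F84 model with bootstrap support, GC-skew profiling
    to locate the replication terminus, and a two-species coalescent simulator
    that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
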