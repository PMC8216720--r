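Package: cutscope
Title: Cut-Site Discovery and Indel Quantification for CRISPR Start-Codon Editing
Version: 0.1.0
Authors@R:
    person("cutscope", "developers", email = "cutscope@example.org", role = c("aut", "cre"))
Description: Tools for analysing CRISPR/Cas9 start-codon disruption experiments:
    a gap-tolerant digenome-seq cut-site caller built on strand-specific
    read-start pileups with filtering and a combined-strand cut-site score;
    guide-homology and PAM based off-target classification with genomic
    context annotation; amplicon deep-sequencing indel quantification with
    inserted-base composition and Kozak-context assessment; genomic-DNA-mass
    based normalisation of editing efficiency; and an in-silico restriction
    digest screen for start-codon indels. A synthetic-data generator produces
    toy genomes, Cas9 digestion read sets with known cut-site truth, and
    amplicon read sets with a configurable indel spectrum, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
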