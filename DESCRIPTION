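Package: cagmosaic
Title: Quantification of Somatic CAG Repeat Instability from Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies somatic instability of the HTT exon-one CAG repeat
    from deep amplicon sequencing. Reads are decomposed into their
    (CAG)n(CAACAG)m(CCGCCA)k(CCG)p(CCT)q repeat structure, inherited alleles
    are called from the read-length histogram with stutter-aware peak
    calling, and per-allele somatic expansion is summarised as the ratio of
    CAG expansions (reads 1-10 repeats longer than the inherited allele,
    relative to reads at the inherited length). A branching-process PCR
    simulator provides a single-molecule stutter baseline that separates
    genuine somatic expansion from amplification noise, and cohort-level
    linear models relate the expansion ratio to inherited CAG length and age
    at sampling within clinical allele categories. A synthetic-data module
    generates FASTQ read sets and cohort tables with the statistical
    structure the analysis assumes, so the whole pipeline is testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
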