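Package: podmr
Title: Parent-of-Origin Differentially Methylated Region Calling from
    Bisulfite Sequencing Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects parent-of-origin biased DNA methylation from
    targeted bisulfite sequencing cytosine counts. Implements a trio
    mode that contrasts pooled maternal and paternal uniparental-disomy
    samples against biparental controls, a hemizygous-deletion mode
    that contrasts the exposed single parental allele of a deletion
    carrier against dizygous controls, a targeted re-scan for small
    (2-4 CpG) candidate regions with SNV masking and cross-tissue
    concordance checks, and a run-of-homozygosity screen for isodisomy.
    Ships a synthetic allele-specific methylation data generator with
    planted differentially methylated regions and binomial read
    sampling for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
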