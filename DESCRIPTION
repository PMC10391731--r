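Package: umiquant
Title: Ultrasensitive Quantification of Cre-Recombined Alleles from
    UMI-Barcoded Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for barcoded amplicon
    sequencing of a three-allele locus (wildtype Braf, native Braf-CA and
    Cre-recombined, activated Braf-CA). Reads carrying 12-nt unique
    molecular identifiers (UMIs) are adapter-trimmed, quality-filtered,
    assigned to alleles by banded edit distance against the three amplicon
    references, collapsed into barcode families (>= 3 reads per UMI), and
    denoised with a per-class family floor before estimating the
    activation prevalence and the mutant-cell fraction with binomial
    (Wilson) uncertainty intervals. A fully reproducible amplicon-library
    simulator with a per-cycle PCR substitution error model and a truth
    sidecar provides ground-truth test data emulating heterozygous
    Braf-CA/+ tissue with a small fraction of recombined cells. Organ
    morphometry helpers (ellipsoid lobe volume, pooled tumor-burden ratio)
    are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
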