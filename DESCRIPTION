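Package: jointsnv
Title: Joint Bayesian Somatic SNV Calling from Multiple Same-Patient
    Tumour Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls somatic single-nucleotide variants jointly across one
    matched normal and several tumour samples from the same patient.
    Instead of repeated pairwise tumour-normal analyses, each genomic
    locus is modelled as a set of per-sample allelic compositions whose
    joint posterior is explored by Gibbs sampling, with Dirichlet priors
    that borrow strength across tumour samples so that shared mutations
    are detected at low variant allele frequencies.  Includes a
    samtools-mpileup reader, a pooled strand-bias Fisher test,
    configurable high-confidence filters, a VCF writer, and a pileup
    simulator for sensitivity and false-positive-rate benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
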