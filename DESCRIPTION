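Package: npolyalign
Title: Repeat-Aware Realignment of Long Reads with Context-Dependent Gap Penalties
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Global read realignment that extends affine-gap Needleman-Wunsch with
    context-dependent penalties for shortening and lengthening n-polymers
    (homopolymers and short tandem repeats with unit length 1-6). Provides
    reference n-polymer annotation, estimation of substitution, affine-gap and
    repeat copy-number penalties from alignment confusion statistics, a
    five-matrix banded dynamic program that follows each read's original
    alignment path, SAM/BAM realignment, Gini-purity read-concordance
    evaluation, phased truth-VCF standardization, and a synthetic-data
    generator for references, reads and phased VCFs with controlled repeat
    content and copy-number error processes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    vcfR,
    withr
Config/testthat/edition: 3
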