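Package: rna5hmc
Title: Region-Level Prediction of 5-Hydroxymethylcytosine RNA Modification
    from k-mer Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds region-level benchmarks of 5-hydroxymethylcytosine (5hmC)
    modified versus unmodified transcript regions from hMeRIP-seq peak
    intervals, trains skip-gram k-mer embeddings on a genome corpus, encodes
    variable-length RNA regions by averaged multi-k embedding concatenation,
    and classifies them with a radial-basis-function support vector machine.
    Includes repeated stratified cross-validation with sensitivity,
    specificity, accuracy, Matthews correlation coefficient, AUROC and AUPR;
    Fisher-style class-separability (J-score) diagnostics; PCA and t-SNE
    feature visualization with a complement-symmetry report; a specificity
    versus sequence-length resolution analysis; and seeded synthetic-fixture
    generators so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    e1071,
    Rcpp,
    rtracklayer,
    GenomicRanges,
    IRanges,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
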