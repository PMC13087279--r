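Package: mscorrect
Title: Minimizer-Space Self-Correction of Noisy Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Self-correction of noisy long sequencing reads (e.g. Oxford
    Nanopore) performed entirely in minimizer space. Reads are sketched into
    ordered lists of universal minimizers at two nested densities; a sparse
    sketch drives ultra-fast all-vs-all recruitment of similar reads by
    seed-and-chaining, a dense sketch re-aligns the recruited reads and
    estimates their divergence from shared-sketch fractions, and the
    surviving alignments are piled into a minimizer-space variation graph
    from which the most supported path is extracted as the corrected read.
    Includes base-space reconstruction of corrected reads, a synthetic
    metagenome/read simulator with ground-truth sketches, and
    correction-quality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    jsonlite,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
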