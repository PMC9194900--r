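Package: wgdtrace
Title: Detection, Dating and Fractionation Analysis of Ancient Whole-Genome
    Duplications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to reconstruct paleopolyploidy from gene order and
    sequence homology: max-gap chaining of colinear (syntenic) blocks from
    homolog hit tables, Nei-Gojobori estimation of synonymous substitution
    rates (Ks) for anchor pairs, decomposition of Ks distributions into
    normal mixture peaks with lineage rate correction and calibration-based
    event dating, colinear depth-ratio and subgenome inference, event-related
    multi-genome alignment tables, genomic fractionation statistics
    (loss-run spectra with geometric fits, sliding-window retention, and the
    P-index allo/autopolyploidy diagnostic), and gene-tree topology support
    counting. A genome-evolution simulator with exact ground truth (placed
    polyploidies, lineage rates, run-length gene loss) exercises the whole
    pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
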