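Package: cellclades
Title: Cladistic Inference of Cell-Type Homology from Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring evolutionary relationships between cell types
    from single-cell transcriptomic and chromatin-accessibility data. Cell types
    are treated as taxa and transcription-factor expression as binary
    presence/absence characters; maximum-parsimony trees are inferred with an
    exact Fitch-based search (exhaustive or branch-and-bound) or a
    nearest-neighbour-interchange heuristic. Includes quality-control filtering
    and normalization of count matrices, Wilcoxon marker detection with
    fold-change thresholds, shared-program extraction between focal cell types,
    correlation/Ward expression dendrograms, TF-IDF/LSI chromatin-accessibility
    dendrograms with promoter exclusion, phylostratigraphic gene-age
    partitioning, cross-species character harmonization through ortholog maps,
    and a negative-binomial simulator with a planted cell-type phylogeny for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    ape,
    stats,
    tools,
    utils,
    methods,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
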