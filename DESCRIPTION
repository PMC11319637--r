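Package: ltrsubfam
Title: Discovery and Classification of LTR Retrotransposon Subfamilies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for refining the classification of long terminal repeat
    (LTR) retrotransposon families such as the MLT2 group of HERVL
    endogenous retroviruses. The package trains substitution and gap rates
    between genomic repeat instances and family consensus sequences,
    competitively partitions genomic sequence among candidate consensuses so
    that each genome base is assigned to at most one consensus base, detects
    recurrent hybrid elements with shared breakpoints, splits families into
    subfamilies from cohorts of instances whose alignments terminate at a
    shared consensus position, rebuilds consensus sequences by iterative
    majority refinement, and characterises the resulting subfamilies by
    divergence statistics, neighbor-joining phylogenies and cross-species
    insertion-age brackets. A bundled genome simulator with machine-readable
    ground truth exercises the whole pipeline without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
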