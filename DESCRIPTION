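Package: tealdemog
Title: Coalescent Demographic Inference and Conservation Genomics for
    Two-Deme Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Demographic and conservation-genomic analysis toolkit built
    around a two-deme structured-coalescent model family, motivated by
    assessments of threatened waterfowl such as the marbled teal.
    Provides a coalescent simulator with epochs and migration (also used
    as a synthetic-data generator for SNP genotypes and mtDNA
    alignments), folded joint site-frequency-spectrum construction with
    presence/MAF filtering and downsampling, composite-likelihood
    fitting of isolation and isolation-with-migration divergence models
    with AIC model selection and parametric-bootstrap confidence
    intervals, stairway-style piecewise-constant effective-population-
    size reconstruction, nuclear-SNP diversity and structure statistics
    (heterozygosities, F_IS, Weir-Cockerham F_ST with permutation
    tests, KING-robust kinship and unrelated-set selection), and
    mtDNA sequence analyses (haplotype collapsing, diversity, Tajima's
    D, Phi_ST, hierarchical AMOVA, and statistical-parsimony haplotype
    networks).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    ape,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
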