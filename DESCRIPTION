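Package: CAZymap
Title: Polysaccharide Structure Maps, Enzymatic Digestion, and CAZyme
    Expression Overlays
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A graphical knowledge base of plant polysaccharide structures
    linked to the enzymatic activities required for their degradation.
    Represents polysaccharides as rooted trees of sugar residues with typed
    glycosidic linkages and ester substituents, packages sixteen reference
    structures together with parametric generators, derives the set of endo,
    exo, debranching and esterase activities needed to depolymerize each
    structure, and simulates enzymatic digestion as a deterministic rule
    closure with a completeness score. An expression-analysis overlay
    provides quantile normalization, median-polish summarization, moderated
    t-tests with empirical-Bayes variance shrinkage, Benjamini-Hochberg
    adjustment, replicate-aware Pearson-distance k-means clustering, and
    coverage reports that detect induction of complete degradation enzyme
    sets per carbon source.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
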