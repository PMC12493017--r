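Package: AmyloidPaths
Title: Class-Preserving Single-Substitution Paths Between Hexapeptides
    Under a Position-Weight Amyloidogenicity Classifier
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Scores hexapeptides with a 20x6 position-specific amyloid
    effect matrix plus intercept (a linear support-vector-machine decision
    function over the 20 proteinogenic amino acids), classifies them as
    amyloidogenic or non-amyloidogenic, and constructs, for any two
    peptides of the same predicted class, a single-residue-substitution
    path of length at most six whose every intermediate peptide keeps the
    endpoints' class. Also derives per-position amyloidogenicity orderings
    of the residues, audits them against a printed reference table,
    classifies wildcard sequence patterns (such as CxFLWx) by closed-form
    score extremization, and verifies the path construction against an
    independent breadth-first-search oracle on restricted sub-lattices of
    the hexapeptide mutation graph.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Classification, Proteomics, SequenceMatching, GraphAndNetwork
Collate:
    'aaa-constants.R'
    'AmyloidPaths-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'effect-matrix.R'
    'scoring.R'
    'ordering.R'
    'graph.R'
    'pathfinder.R'
    'patterns.R'
    'io.R'
    'show-methods.R'
RoxygenNote: 7.3.3
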