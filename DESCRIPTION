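Package: phylostruct
Title: Resolving Host Population Structure from Pathogen Phylogeny Shape
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates rooted pathogen phylogenies under one- and two-deme
    birth-death-migration processes parameterised through the basic
    reproduction number R0 (next-generation-matrix method), computes eight
    topological tree-shape statistics (cherries, Sackin, Colless, total
    cophenetic index, ladder length, maximum width and depth, width-depth
    ratio) with explicit conventions for unifurcating migration nodes,
    compares their distributions between structured and non-structured host
    populations with two-sample Kolmogorov-Smirnov, Cucconi and
    Podgor-Gastwirth tests, and trains cross-validated classifiers (KNN,
    linear/polynomial/radial SVM, decision trees) that label trees as coming
    from a structured or non-structured host population, including Latin
    hypercube sensitivity designs over R0 and tree size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    class,
    e1071,
    jsonlite,
    lhs,
    rpart,
    stats,
    tools,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
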