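Package: multibalance
Title: Sound Balance Indices for Multifurcating Phylogenetic Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes balance indices for rooted phylogenetic trees with
    arbitrary multifurcations: the Colless and quadratic Colless indices for
    bifurcating trees, the Sackin and total cophenetic indices, and the
    Colless-like family C_{D,f} obtained by combining a dissimilarity D with
    a node-degree weight function f.  Includes machinery to decide when a
    Colless-like index is sound (zero exactly on fully symmetric trees), to
    detect f-size collisions between fully symmetric trees, closed-form
    maxima and maximally unbalanced trees for the recommended weight
    functions, exhaustive enumeration of small tree shapes, Newick
    input/output, random tree generation under the alpha-gamma Markov
    branching model and the uniform model on multifurcating phylogenies,
    null-distribution simulation, percentile estimation and goodness-of-fit
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
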