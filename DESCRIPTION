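Package: halfrec
Title: Exact Closed-Form Solutions of Dividing-by-a-Half Recurrences and
    Phylogenetic Tree Balance Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Solves divide-and-conquer "dividing by a half" recurrences
    x(n) = a*x(ceiling(n/2)) + a*x(floor(n/2)) + P(ceiling(n/2), floor(n/2)),
    with P a bivariate polynomial toll function, in exact finite closed form:
    the solution is expressed through the binary decomposition of n, Bernoulli
    numbers and geometric-type power sums, with every value computed in exact
    rational arithmetic and cross-validated against a memoized direct
    recursion.  The closed formulas are applied to named integer sequences
    (minimum Sackin, Colless and Total Cophenetic indices, maximum rooted
    Quartet index of maximally balanced trees, Walsh Lebesgue constants,
    bitwise AND/XOR/OR convolution sums) and to a phylogenetics layer that
    computes and normalizes the Sackin, Colless, Total Cophenetic and rooted
    Quartet balance indices on arbitrary rooted trees in Newick format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    ape,
    jsonlite,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
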