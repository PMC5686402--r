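Package: isogen
Title: Exhaustive Constitutional Isomer Generation and Chemical Space Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Complete and non-redundant enumeration of constitutional isomers
    from exact or fuzzy molecular formulae by orderly generation over
    bond-order matrices, with forbidden-substructure (badlist) and required-
    substructure (goodlist) filtering. Builds virtual compound libraries of
    alpha-amino acids and nucleoside analogues, supports symmetry-aware
    heteroatom substitution via automorphism orbits, computes additive
    molecular descriptors (logP, van der Waals volume, rule-based pKa,
    Wiener index), and performs adaptive-alphabet analysis comparing a
    reference set of monomers against randomly sampled same-size sets with
    respect to range and evenness of physico-chemical properties.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
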