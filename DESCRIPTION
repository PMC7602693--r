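Package: mpclad
Title: Equal-Weights Maximum Parsimony Analysis of Discrete Morphological Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for cladistic analysis of discrete morphological character
    matrices under equal-weights maximum parsimony: NEXUS/TNT matrix input and
    output with state-set cell semantics (missing, inapplicable, polymorphic),
    Wagner random-addition starting trees, tree bisection and reconnection
    (TBR) branch swapping with tree buffering and zero-length branch
    collapsing, exact (exhaustive and branch-and-bound) search for small taxon
    sets, strict consensus, Bremer decay and parsimony jackknife branch
    supports, generalized Fitch/Sankoff character-state optimization for
    ordered (additive) and unordered characters on binary or polytomous trees,
    ACCTRAN/DELTRAN ancestral-state resolution with apomorphy lists, and
    per-character and ensemble homoplasy diagnostics (length, consistency and
    retention indices). A matrix simulator evolves characters on a known tree
    with controllable homoplasy and injects missing, inapplicable and
    polymorphic cells for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
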