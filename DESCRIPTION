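Package: multiphi
Title: Integrated Information and Cause-Effect Structures for Discrete
    Dynamical Systems with Multi-Valued Elements
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Causal analysis of discrete Markovian dynamical systems whose
    elements may take more than two states. Networks are specified by a
    state-by-state transition probability matrix together with the number of
    states of each element. The package unfolds the cause-effect structure
    (CES) of a system in a state, computes mechanism-level integrated
    information (phi) with the absolute intrinsic difference measure over
    tripartitions, and system-level integrated information (Phi) as the sum
    of phi lost under the minimum information partition. It further provides
    Boolean conversions of multi-valued logical models (Van Ham, Faure-Kaji,
    Tonello), coarse-graining of binary models back to multi-valued ones,
    random-network generators, and batch survey drivers, including the
    p53-Mdm2 regulatory network model as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
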