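Package: kinsolv
Title: Kinetic Solvent Effect Prediction from Condensed Graphs of Reaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts solvation free energy and enthalpy of activation
    (ddG/ddH of activation at 298 K, kcal/mol) for reaction-solvent pairs
    from atom-mapped reaction SMILES and solvent SMILES. Implements the
    condensed graph of reaction (CGR) representation, a dual directed
    message-passing neural network encoder with a feed-forward regression
    head, a transfer-learning and ensembling protocol, leakage-safe
    reaction and solvent data splits, data curation filters, and
    transition-state-theory conversions between activation free energies
    and relative rate constants. Includes a synthetic fixture generator
    with templated radical reactions and a closed-form surrogate target
    so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
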