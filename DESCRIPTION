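Package: qcfill
Title: Quantum-Chemical Validation of AI-Suggested Retrosynthesis Steps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validates low-confidence single-step retrosynthesis predictions by
    constrained elementary-step exploration over a pluggable energy backend.
    Parses plain and atom-mapped SMILES into molecular graphs, builds sanitized
    3D structures with charge and spin-multiplicity assignment, enumerates
    constrained bimolecular reactive trials (optionally pruned by atom-to-atom
    mapping), aggregates discovered elementary steps into a compound-level
    reaction network, issues thermodynamic and kinetic feasibility verdicts
    based on an endothermicity filter and a Maxwell-Boltzmann kinetic-dominance
    test, updates prediction confidences, and budgets the computation with a
    core-hour scaling model. Ships a deterministic surrogate backend so the
    entire pipeline is testable without an electronic-structure program, plus
    an adapter contract for external semiempirical codes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
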