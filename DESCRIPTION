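Package: pbpkfba
Title: Multiscale Coupling of Genome-Scale Metabolic Networks and
    Physiologically Based Pharmacokinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based modelling kernel (flux balance analysis,
    flux variability, reaction and gene knockouts, essentiality scans,
    hit-and-run flux sampling) for genome-scale metabolic networks,
    coupled to a whole-body perfusion-limited physiologically based
    pharmacokinetic (PBPK) model and an ODE model of cortisol-driven
    nuclear-receptor regulation of CYP3A4. The three layers are joined
    by a quasi-steady-state loop in which tissue drug concentrations
    tighten metabolic flux bounds (feedforward) and the maximal
    glutathione production computed by linear programming scales the
    conjugation clearance of a toxic metabolite (feedback). Includes
    readers for SBML Level 3 FBC and a plain tabular reaction format,
    deterministic toy-network fixtures including a miniature liver
    glutathione model, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    boot,
    deSolve,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
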