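Package: solvselect
Title: Solvent Selection and Isolation Mass-Balance Simulation for API Purification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a nine-stage workflow for choosing crystallization and
    wash solvents for active pharmaceutical ingredient (API) isolation.
    Crystallization solvents are ranked by yield and solvent consumption under
    safety (ICH residual-solvent class) and suspension-density constraints;
    wash solvents are screened with physicochemical, safety and sustainability
    filters and ranked by non-dominated (Pareto) sorting of API versus impurity
    solubility; binary crystallization-to-wash solubility curves flag
    dissolution risk. Two mass-balance simulators predict isolation
    performance: an ideal displacement-washing model and a higher-fidelity
    model combining constant-pressure (Darcy) cake filtration with
    advection-dispersion washing. Ships a paracetamol/acetanilide/metacetamol
    case study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
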