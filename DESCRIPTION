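Package: btbpk
Title: Physiologically Based Pharmacokinetics of the Brain and Brain Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A physiologically based pharmacokinetic (PBPK) model of the central
    nervous system with nine compartments (brain microvascular plasma, brain
    extracellular and intracellular fluid, cell membrane, lysosomes, and four
    cerebrospinal-fluid compartments) extended with five brain-tumor
    compartments inserted between plasma and the lateral ventricles. Drug
    transport across the blood-brain and blood-tumor barriers is assembled from
    physicochemical properties (pH partitioning, aqueous diffusivity,
    transmembrane permeability) and species physiology. Includes empirical
    plasma forcing functions with inter-individual and residual variability, a
    two-stage "handshake" estimation workflow that extracts paracellular
    pore-size and active-efflux-clearance fold changes of the blood-tumor
    barrier from unbound extracellular-fluid concentration-time data, visual
    predictive checks, relative-accuracy statistics, and a synthetic
    microdialysis study generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
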