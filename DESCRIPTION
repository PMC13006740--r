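Package: nanoabm
Title: Agent-Based Simulation of Drug-Loaded Nanoparticle Cancer Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiscale agent-based simulation of tumor response to
    drug-loaded nanoparticle (NP) therapy. Off-lattice cell agents with
    oxygen-dependent proliferation and necrosis grow in a 2D diffusive
    microenvironment; extracellular NPs diffuse in from a vascular
    (Dirichlet) far-field, are internalized by saturable endocytosis, and
    release drug through an age-structured m-state compartment cascade.
    Intracellular drug modulates cycling (cytostatic) or apoptosis
    (cytotoxic) through Hill or AUC pharmacodynamics, and internalized NPs
    are heritable at cell division. Includes replicate-ensemble and
    parameter-sweep drivers for NP design and dosing-schedule experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    ggplot2,
    optparse
Config/testthat/edition: 3
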