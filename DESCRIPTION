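Package: rcdmlp
Title: Range-Corrected Delta Machine Learning Potentials with Umbrella
    Sampling Free Energy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and trains range-corrected delta machine learning
    potentials (Delta-MLPs) that correct a cheap base potential toward an
    expensive target potential in QM/MM-style atomic systems.  Provides the
    restricted graph topology in which MM-MM edges are excluded and MM
    species are remapped, many-body (ACE/MACE-style) and two-body-descriptor
    (DeepPot-style) correction energy models with analytic forces, committee
    training with the iterative "simplify" data-selection workflow and
    end-state augmentation, a synthetic two-basin reaction surrogate with
    Langevin umbrella sampling, and a free-energy analysis stack: MBAR,
    histogram free energy surfaces, weighted thermodynamic perturbation
    (wTP), its multi-reference generalization (gwTP), reweighting-entropy
    diagnostics, and density-of-states smoothing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
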