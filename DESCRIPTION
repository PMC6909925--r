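Package: fcmsim
Title: Qualitative Cell-State Simulation on Signed Concept Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cellular reprogramming, differentiation and disease
    phenotypes as steady states of a signed, weighted concept network
    (a fuzzy cognitive map) iterated through a bounded squashing function
    under clamping interventions: reprogramming recipes, gene knockouts and
    fractional pharmacological inhibition. Provides thresholded expression
    calling, bias-adjusted exact binomial validation against literature
    expectation profiles, exact Mann-Whitney genotype comparison,
    dose-response screening with two-phase treatment scheduling, and
    single-variable biomarker discovery with stratified cross-validation.
    Ships a curated infantile-onset Pompe disease (IOPD) network covering
    reprogramming factors, pluripotency and skeletal-muscle marker panels,
    the GAA/lysosomal-glycogen disease axis, mTORC1 signalling,
    mitochondrial function, autophagy/mitophagy and calcium handling, plus
    a random-network generator for property testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'ConceptNetwork-class.R'
    'network-io.R'
    'network-stats.R'
    'random-network.R'
    'iopd-fixture.R'
    'SimulationConfig-class.R'
    'clamps.R'
    'StateTrajectory-class.R'
    'dynamics.R'
    'SteadyStateProfile-class.R'
    'replicates.R'
    'Recipe-class.R'
    'recipes.R'
    'treatments.R'
    'dose-response.R'
    'expression-calls.R'
    'binomial-validation.R'
    'mann-whitney.R'
    'literature-profiles.R'
    'profile-dataset.R'
    'biomarkers.R'
    'cross-validation.R'
    'cli.R'
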