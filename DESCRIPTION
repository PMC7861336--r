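Package: deepscene
Title: Deep Active Inference Agents for Hierarchical Scene Construction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation of deep (two-level) active inference agents performing
    a hierarchical scene-construction task with random-dot-motion stimuli.
    Implements exact categorical-distribution primitives, construction of the
    two-level partially observed Markov decision process (likelihoods,
    transitions, preferences, priors, single-step policies), variational state
    estimation by fixed-point message passing, policy evaluation via variational
    and expected free energy (risk, ambiguity, epistemic and instrumental
    value), the two-level scheduler that exchanges empirical priors and
    inferred observations between a fixational motion-sampling level and a
    saccadic scene-inference level, and batch experiment drivers that sweep
    sensory precision and prior-belief strength to measure categorization
    latency, accuracy, and fixational dwell time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
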