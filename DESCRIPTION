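Package: isokie
Title: Multi-Element Kinetic Isotope Effect Inference for Dehydrochlorination
    Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts and measures multi-element (carbon, chlorine, hydrogen)
    kinetic isotope effects for base-promoted dehydrochlorination reactions on
    toy molecular systems with analytic Hessians. Implements semiclassical
    Bigeleisen kinetic isotope effects from Cartesian Hessian vibrational
    analysis, compound-average (bulk) enrichment factors, hybrid
    primary/secondary bulk assembly, Rayleigh regression of simulated batch
    degradation experiments, umbrella-sampling free-energy profiles
    reconstructed with the weighted histogram analysis method, and
    path-integral bead-quantized free-energy corrections with
    mass-perturbation free energy perturbation, together with the synthetic
    data generators that emulate the corresponding laboratory and simulation
    protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
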