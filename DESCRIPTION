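Package: standforge
Title: Forest Stand Biomass Accounting and Spatial Point-Pattern Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for large forest dynamics plots: multi-pool aboveground
    biomass accounting (live trees via allometric equations with
    substitution and capping rules, snag frustum volumes, shrub patch
    extrapolation, planar-intercept coarse woody debris, Brown fine-fuel
    classes, litter and duff), metabolic-scaling-theory fits to diameter
    distributions, and Monte Carlo spatial point-pattern inference
    (Ripley's K and L functions with isotropic edge correction, complete
    spatial randomness and population-independence null models via
    toroidal shifts, Loosmore-Ford goodness-of-fit). A seeded synthetic
    stand generator reproduces the statistical structure of an old-growth
    mixed-conifer census so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
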