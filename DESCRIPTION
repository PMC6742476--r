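Package: rodscale
Title: Surface-to-Volume Scaling and Aspect-Ratio Homeostasis in Rod-Shaped Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the allometric scaling of bacterial cell
    surface area with volume, S = gamma * V^(2/3), and for simulating the
    single-cell mechanism that maintains it. Provides closed-form
    spherocylinder and prolate-spheroid geometry with forward and inverse
    mappings between the scaling prefactor gamma and the cell aspect ratio;
    log-log power-law fitting of shape tables with free or fixed exponent;
    a stochastic single-cell growth-division simulator coupling exponential
    elongation, threshold accumulation of the division protein FtsZ with a
    width-proportional threshold, and a surface-synthesis width-control ODE;
    ensemble protocols for nutrient shifts, FtsZ knockdown, MreB depletion
    and antibiotic filamentation; and generators for synthetic shape,
    newborn and lineage tables with the statistical structure the analysis
    assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
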