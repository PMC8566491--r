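Package: mouthfeel
Title: Predicting Perceived Thickness of Liquid Foods from Shear Rheology
Version: 0.1.0
Authors@R: person("mouthfeel", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts the sensory "thickness" of shear-thinning liquid foods
    from their rheology. Fits power-law (Ostwald-de Waele) flow curves,
    models the dynamic squeeze flow of the fluid trapped between the moving
    tongue and the palate to obtain the total shear stress on the tongue,
    and relates that stress to panel thickness scores through logarithmic
    (Weber-Fechner) and power-law (Stevens) psychophysical laws. Ships the
    rheology and sensory-panel dataset of 20 liquid samples used to
    calibrate the model, synthetic-data generators with known ground truth,
    and a command-line interface reproducing the full analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
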