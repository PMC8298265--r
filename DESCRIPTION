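Package: pulmonet
Title: One-Dimensional Pulmonary Circulation Modelling with
    Structured-Tree Microvasculature and a Reduced Left-Atrial Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates pulse-wave propagation in the large pulmonary
    arteries and veins with a nonlinear one-dimensional solver,
    closes the microvascular gap between terminal arteries and veins
    with mirrored structured-tree two-port admittance boundary
    conditions, and couples the vein outlets to a reduced-order
    (0D) left atrium with a mitral-valve orifice model via an
    explicit relaxed cosimulation scheme.  Includes wave-intensity
    analysis, pulse-wave velocity and haemodynamic summary tools,
    and scenario presets for a healthy control, atrial fibrillation
    and acute mitral regurgitation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    signal,
    optparse
Config/testthat/edition: 3
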