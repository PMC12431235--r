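Package: ecapsim
Title: Semi-Analytic Modelling of Evoked Compound Action Potentials in
    Multifascicular Nerves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes extracellular signals from spatially extended neural
    sources with a reciprocity-theorem lead-field approach. Provides
    single-fiber action potential (SFAP) computation by convolution of the
    second temporal derivative of the transmembrane potential with a
    velocity-reparameterized sensitivity function, a closed-form solution
    for Gaussian action potentials and Gaussian electrode sensitivity
    profiles with its short- and long-action-potential limit cases, a
    point-source summation reference method, diameter-dependent fiber
    recruitment with titration curves and threshold rescaling, assembly of
    the evoked compound action potential (eCAP) of a multifascicular nerve
    from per-fascicle exposure functions, a synthetic nerve and cuff
    electrode generator, and inverse recovery of fiber-diameter
    distribution parameters from a reference eCAP by derivative-free
    pattern search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
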