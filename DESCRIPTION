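Package: osteoadapt
Title: Orthotropic Second-Gradient Continuum Simulation of Bone Remodeling
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quasi-static two-dimensional finite-element simulator of bone
    functional adaptation in an orthotropic strain-gradient (second-gradient)
    elastic continuum.  The material symmetry orientation and a subset of the
    orthotropic stiffnesses evolve in time, driven by diffusing energy-based
    mechanobiological stimuli, so that the simulated trabecular architecture
    realigns with the principal strain directions (the trajectorial reading of
    Wolff's law).  Includes a C1-continuous tensor-product B-spline
    discretization on rectangular domains, frictionless penalty pin contact,
    two ready-made loading scenarios (cantilever bending and three-point
    flexure), reaction-diffusion stimulus fields, trajectorial alignment
    diagnostics, and VTK/CSV field export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    splines,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
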