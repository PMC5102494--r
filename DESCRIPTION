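Package: oxywindow
Title: Oxygen Transport Design Models for Gas-Exchange Microfluidic Devices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design and analysis of crossed-channel PDMS microfluidic devices
    that desaturate flowing red blood cell suspensions through a gas-exchange
    window. Provides a closed-form one-dimensional advection-diffusion-
    permeation model with Peclet-number design curves, a three-dimensional
    steady conjugate oxygen transport solver on graded hexahedral meshes with
    nonlinear hemoglobin binding (Hill equation), optically weighted oxygen
    drop metrics, and geometry sweep drivers for device optimization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
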