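Package: usforward
Title: Forward-Problem Simulation of Ultrasound-Powered Piezoelectric Implants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-dimensional computational framework for the ultrasound
    forward problem around deeply implanted piezoelectric devices. Solves the
    full-domain scattering integral equation (lossy free-space Green kernel,
    density and propagation-coefficient contrast functions, conjugate-gradient
    iteration with the Hermitian adjoint) on graded multi-resolution orthogonal
    meshes, and traces acoustic rays through tissue interfaces with Snell
    refraction, impedance-based amplitude splitting and power-law attenuation.
    Includes grey-level phantom segmentation, synthetic water-tank and layered
    breast scenes, lens/disk/cone double-piezo-layer implant models, Gaussian
    pulse and harmonic excitation, echo synthesis and echo metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png,
    tiff
Config/testthat/edition: 3
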