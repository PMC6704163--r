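Package: octsim2d
Title: Two-Dimensional Spectral-Domain OCT Image-Formation Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-dimensional spectral-domain optical coherence
    tomography (OCT) images from first principles. A Gaussian fiber mode is
    propagated through an afocal lens train with Fresnel integrals and a
    cylindrical-lens Debye-Wolf diffraction integral, scattered by the sample
    either exactly (infinite-cylinder series solution) or numerically (a
    convergent Born-series Helmholtz solver on a refractive-index grid with
    absorbing boundaries), propagated back, and coupled into the detection
    fiber for every sampled wavenumber. A-scans and B-scans are reconstructed
    by inverse discrete Fourier transform of the cross-correlation
    interferogram, with the depth-aliasing limit of the spectral sampling made
    explicit. Includes generators for synthetic phantoms (cylinder clusters,
    ziggurat profiles, dentin-tubule slabs) and a mean-free-path diagnostic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png,
    optparse
Config/testthat/edition: 3
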