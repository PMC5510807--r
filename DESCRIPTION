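Package: ciliaflow
Title: Micro-Bead Tracking Analysis of Cilia-Driven Flow and the Wall
    Shear-Stress Efficiency Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for quantifying the fluid flow generated by beating
    respiratory cilia from high-speed video-microscopy. Provides ciliary
    beat analysis (beat frequency by spectral and kymographic methods,
    beat amplitude from tip landmarks, metachronal wavelength by phase
    regression along the ciliated edge, cilia density from grey levels),
    micro-bead segmentation and trajectory linking with straightness and
    direction filters, a two-dimensional envelope-model Stokes flow
    simulator with a Navier slip wall condition and massless-tracer
    advection, parabolic fitting of the bead velocity profile, and the
    wall shear-stress efficiency index tau_w = 2*mu*Uw/h. A synthetic
    movie generator with known ground truth makes every stage testable
    without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    EBImage,
    deSolve,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
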