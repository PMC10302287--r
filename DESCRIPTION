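Package: vlpsizer
Title: Sizing Virus-Like Particles from Gas-Phase Electrophoresis and Cryo-TEM Images
Version: 0.1.0
Authors@R:
    person("VLP", "Sizer Developers", email = "vlpsizer@example.org", role = c("aut", "cre"))
Description: Tools for characterizing quasi-spherical virus-like particles
    (VLPs) from two complementary measurements. For nano-electrospray gas-phase
    electrophoretic mobility analysis (nES-GEMMA / nES-DMA), the package maps
    classifier voltages to electrophoretic-mobility (EM) diameters through the
    cylindrical-DMA transfer-function centroid and the Stokes-Millikan relation
    with Cunningham slip correction, assembles median spectra from repeated
    scans, fits Gaussian monomer peaks, normalizes particle counts, and runs
    the pH-series statistics. For cryo-TEM, it aligns and averages boxed
    particle images into a 2D class average, builds a grey-value intensity
    surface, extracts sub-pixel iso-height contour sections, and determines an
    unbiased particle diameter by robust circle fitting with outlier trimming.
    Seeded synthetic-data generators (spherical-shell projections, mobility
    scans with Poisson counting noise, tip-convolved AFM topographs) make every
    stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
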