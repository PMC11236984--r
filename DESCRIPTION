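Package: tirfsmt
Title: Simulation and Quantification of Single-Molecule TIRF Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic single-molecule total internal reflection
    fluorescence (TIRF) movies with a physically parameterized emitter,
    evanescent-field, point-spread-function and EMCCD camera model, and
    provides the matching quantification chain: spot detection and subpixel
    localization, intensity measurement in photons, trajectory linking,
    immobile-particle filtering, channel registration, mean-squared
    displacement diffusion analysis, Gaussian-mixture intensity
    stoichiometry, alternating-laser-excitation single-molecule FRET
    corrections (leakage, direct excitation, gamma), labeling-ratio
    corrected dimerization fractions, image-resolution estimation by
    decorrelation analysis and actin-corral size statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    igraph,
    tiff,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
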