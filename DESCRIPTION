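Package: ctclab
Title: Charge-Transfer Complex Spectrophotometry, QTAIM Descriptor Algebra
    and Promolecular NCI Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis chain for UV-Vis charge-transfer (CT) complex studies:
    spectrum handling and band location, conversion between wavelength and
    photon energy, Gaussian convolution of excited-state lists into simulated
    spectra, stoichiometry determination by Job's continuous-variation and
    photometric molar-ratio methods, Benesi-Hildebrand association-constant
    fitting with standard Gibbs free-energy change, ICH-style assay validation
    statistics (calibration linearity, LOD/LOQ, precision, recovery), algebra
    and Rozas classification of QTAIM bond-critical-point descriptors with
    local-virial self-consistency checks and counterpoise (BSSE) interaction
    energy arithmetic, and a wavefunction-free promolecular electron-density
    engine producing reduced-density-gradient (RDG) and sign(lambda2)*rho
    fields on regular 3-D grids with Gaussian cube and NCI scatter output.
    Includes synthetic-data generators with known ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
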