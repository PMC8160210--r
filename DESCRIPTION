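Package: hexabind
Title: Global Analysis of Multi-Site Ligand-Binding Titrations and Allosteric Enzyme Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for deciding how many classes of non-equivalent binding sites an
    oligomeric protein exposes in solution. Implements exact equilibrium speciation for
    sequential 1-, 2- and 3-step binding schemes with ligand depletion, statistical
    (no-cooperativity) reference schemes, observation models for fluorescence, circular
    dichroism, microscale thermophoresis and isothermal titration calorimetry,
    pre-fit signal corrections (time drift, ionic-strength quench, Savitzky-Golay
    spectral smoothing, two-range curve stitching), global multi-curve nonlinear
    fitting with profile-likelihood 3-sigma intervals, model discrimination by
    Wald-Wolfowitz runs test, Akaike weights and F-tests, allosteric and competitive
    rate laws for enzyme kinetics, and seeded synthetic-data generators for the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
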