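Package: tetherlab
Title: Single-Molecule and Fluorescence-Fluctuation Analysis of Vesicle
    Tethering Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the dynamics and stoichiometry of
    multi-subunit vesicle-tethering complexes (such as the exocyst) from
    single-molecule fluorescence data.  Implements dual-color fluorescence
    cross-correlation spectroscopy (FCCS) with a two-component diffusion
    model and joint three-curve fitting, a software multiple-tau
    correlator, photobleaching step counting with a GFP standard curve for
    molecule counting, corrected two-color single-particle coincidence,
    TIRF vesicle-fusion event timing, mean-squared-displacement
    diffusivity estimation, and an octamer/tetramer/free-subunit
    state-abundance model.  A synthetic-data generator with full ground
    truth stands in for the microscope so that every analysis stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
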