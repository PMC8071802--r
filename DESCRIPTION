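Package: stalkpath
Title: Minimum Free-Energy Paths for Membrane Fusion Stalk Formation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for computing minimum free-energy paths (MFEPs) of
    membrane-morphology transitions in a collective density order parameter.
    Implements cloud-in-cell mapping of particle configurations onto a
    collocation grid, field-theoretic umbrella sampling with its
    chemical-potential estimator, the zero-temperature string method with
    Allen-Cahn relaxation and cubic-spline reparameterization, thermodynamic
    integration of the free-energy profile, morphological observables of
    fusion stalks (intermembrane distance, stalk diameter, azimuthal density
    maps), and the Derjaguin model for the dehydration free energy of apposed
    vesicles. Ships analytic free-energy functionals, constructed membrane
    density fields and a toy Langevin sampler so the whole pipeline is
    exercisable and testable without molecular dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
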