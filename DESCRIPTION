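Package: littplan
Title: Laser Interstitial Thermal Therapy Simulation and Dosimetry Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates laser-induced interstitial thermotherapy (LITT) of soft-tissue
    tumors with a modified Pennes bioheat model: Beer-Lambert photon deposition from a
    Gaussian-profile bare-fiber beam, temperature-dependent thermal conductivity and
    apparent volumetric heat capacity (water evaporation), piecewise-polynomial
    temperature-dependent blood perfusion for healthy and tumor tissue,
    coagulation-state blending of optical properties, and a dwell-time threshold
    necrosis model. Provides synthetic voxel and axisymmetric phantoms standing in for
    segmented patient anatomies, an implicit finite-volume solver with Dirichlet and
    vessel-convection boundaries, ablation and organ-at-risk metrics, and a laser
    power-by-time dose-grid optimizer selecting the minimum-power setting that ablates
    a target fraction of tumor plus safety margin while keeping organs at risk below a
    temperature limit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    tools,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
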