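Package: stereovasc
Title: Design-Based Stereology of Capillary Networks with Synthetic Phantoms
Version: 0.1.0
Authors@R:
    person("stereovasc", "developers", email = "stereovasc@example.org",
           role = c("aut", "cre"))
Description: Tools for design-based stereological quantification of capillary
    networks in a convex reference region: Cavalieri point counting for region
    volume, and length density, volume fraction and surface density of the
    capillary phase from isotropic uniform random (IUR) sections probed with
    unbiased counting frames, point grids and test line grids. Includes a
    synthetic 3D capillary phantom generator with exact closed-form ground
    truth for validating the estimators, a virtual microtome producing slab
    stacks and IUR section planes with elliptical vessel profiles, and
    group-comparison statistics (one-way ANOVA and pairwise t tests) that
    operate on raw per-animal values or on published summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
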