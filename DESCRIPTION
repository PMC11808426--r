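Package: shakeflask
Title: Engineering Characterization of Orbitally Shaken Flasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Desk-scale engineering computations for orbitally shaken
    Erlenmeyer flasks: dimensionless groups (Reynolds, film Reynolds,
    modified Newton and phase numbers), classification of in-phase versus
    out-of-phase operation, volumetric power input and kLa correlations,
    an exponential out-of-phase correction of the power-input correlation,
    effective shear rates for shear-thinning (power-law) broths with the
    associated effective-viscosity fixed point, and diffusion coefficients
    of small solutes via the Stokes-Einstein-Gierer-Wirtz estimation.
    Also post-processes two-phase (volume-of-fluid) flow snapshots on
    structured grids into energy dissipation rates, volumetric power
    input, interfacial area, eddy-cell kLa values, strain-rate based
    shear estimates and liquid contact lines, with a synthetic field
    generator providing closed-form reference solutions for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
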