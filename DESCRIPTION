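Package: pdsieve
Title: Hindered-Diffusion Modelling of Plasmodesmal Sugar Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative test of the polymer-trap hypothesis of active
    symplasmic phloem loading. Models hindered diffusion of sucrose and
    raffinose-family oligosaccharides through plasmodesmata at the bundle
    sheath - intermediary cell interface under three hypothetical pore
    substructures (sub-nano channels, annular slit, hydrogel), computes
    hydrodynamic radii from diffusivities via the Stokes-Einstein relation,
    aggregates per-pore hindrance to interface-level effective diffusion
    coefficients, converts leaf carbon-export rates to interface flux
    densities, and inverts flux constraints to required concentration
    potentials. Includes a synthetic two-compartment tracer-equilibration
    simulator with effective-diffusion-coefficient recovery and lognormal
    parameter-scenario generation for sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
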