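Package: spotfluence
Title: Proton Spot Fluence Characterization from Field Size Factors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Commissioning tools for the in-air lateral fluence of a scanned
    proton pencil beam behind a fixed range shifter. Models the single-spot
    fluence as a double Gaussian, predicts field size factors (FSFs) of
    uniform square spot fields by lattice summation with virtual-source
    divergence, and fits the per-plane Gaussian widths and shared halo weight
    from measured FSF tables by grid search with derivative-free refinement.
    Includes the spiral spot-delivery pattern with control points that yields
    all FSFs of one energy and plane from a single delivery, monotone
    interpolation of fitted parameters across the machine energy-layer list,
    one-at-a-time parameter sensitivity reports, and a synthetic campaign
    generator with known truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
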