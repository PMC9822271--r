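Package: fdclass
Title: Classification and Batch Statistics for AFM Force-Distance Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for atomic force microscopy (AFM) force-distance
    curves from single-molecule force spectroscopy, built around the
    biotin-streptavidin model system probed with a PEG-tethered ligand. Detects
    tether-rupture (adhesion) events on baseline-corrected retract traces,
    classifies every curve into one of six interaction groups plus an artifact
    group from the maximum adhesion force and the number of rupture peaks, and
    computes batch-level statistics: type frequencies, adhesion-force
    histograms, windowed temporal-drift profiles and the success rate. Includes
    a physics-based synthetic curve generator (worm-like-chain tether pulls
    with type-conditioned rupture-force distributions, instrument noise,
    baseline tilt and artifact injection) with presets for a pristine
    streptavidin surface and a biotin-albumin-blocked control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse
Config/testthat/edition: 3
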