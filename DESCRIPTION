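Package: cartindent
Title: Cartilage Indentation Biomechanics and Subchondral Bone Volume Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for flat-punch stress-relaxation indentation of
    articular cartilage and repair tissue. Segments ramp-hold-unload indentation
    records into protocol phases, smooths load-displacement data with a
    Savitzky-Golay filter, fits the upper fraction of the loading curve with an
    R-squared quality gate, and converts fitted slopes and equilibrium loads into
    tangent and equilibrium elastic moduli using the layered-elastic (Hayes)
    correction kappa(alpha, nu) for a flat-ended cylindrical indenter on a thin
    elastic layer bonded to a rigid substrate, solved from the governing Fredholm
    integral equation. Also quantifies bone volume fraction (BV/TV) in a
    cylindrical region of interest of a thresholded micro-CT voxel volume, and
    compares outcome measures across experimental groups with ANOVA and Tukey HSD.
    Includes a standard-linear-solid synthetic data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
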