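Package: ielastic
Title: Integrated Elasticity Regression for Parallel-Plate Compression of
    Multicellular Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts elastic moduli from parallel-plate compression
    force-displacement curves of multicellular clusters (tumor spheroids and
    similar samples) whose contact geometry is indeterminate, between planar
    and spherical. Implements the integrated-elasticity (IE) power-law
    regression F = E*C(alpha, x, h)*delta^alpha, whose prefactor interpolates
    between the ideal planar-contact solution (alpha = 1) and the Hertz
    spherical-contact solution (alpha = 1.5), together with full-range and
    two-point linear fits, the Hertz fit, reference-gel (cube) fitting and
    relative-modulus reporting, contour-based geometry metrics (non-planarity
    and smoothness of the upper sample margin), seeded synthetic force-curve
    and silhouette generators, and delimited-text readers for
    MicroTester-style exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
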