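Package: smartegg
Title: Smart's Egg-Shape Model Family: Contours, Main-Axiom Analysis and
    Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the geometric analysis of avian egg profiles with
    Smart's contour model and its modifications (SM, SM^r, SM^B0, SM^B02,
    SM^r2, SM^MA, SM^U). Evaluates every variant through one canonical
    contour form, measures the defining parameters (length L, maximum
    breadth B, breadth offset w, mid-length breadth B0 and the quarter-
    length diameters r and R) from digitized outlines, fits each variant to
    a profile with a mean-percentage-error criterion, checks compliance
    with the extremum ("Main Axiom") constraint that a contour attain
    exactly B/2 at x = w, derives the Axiom-compatible parameter relations,
    computes closed-form volumes of the resulting solids of revolution and
    the length of the volume-equivalent ellipsoid, and generates
    pixel-sampled synthetic profiles spanning the parabola-to-ovoid
    pointed-end continuum for testing. Includes contour file I/O and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
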