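Package: otoshape
Title: Otolith Outline Morphometrics by Wavelet and Elliptic Fourier Shape Coefficients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Shape analysis of fish otoliths (and other two-dimensional objects)
    from calibrated photographs on a dark background. Extracts closed contour
    outlines by intensity thresholding and Moore-neighbour boundary tracing,
    smooths pixel noise, and converts each outline into independent shape
    coefficients by either a discrete wavelet transform of the equidistant-angle
    radial profile or normalized elliptic Fourier decomposition. Includes
    allometric length-standardization of coefficients with interaction
    screening, calibrated size descriptors (Feret length, width, perimeter,
    area), per-group mean shapes, per-angle variance partitioning (intraclass
    correlation), reconstruction-quality curves, and downstream population
    statistics: constrained ordination, distance-based permutation ANOVA, and
    linear-discriminant classification error by cross-validation or bootstrap.
    A synthetic-fixture generator renders otolith-like images with planted
    group and allometry structure so the full pipeline can be exercised
    without real data.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    MASS,
    vegan,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
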