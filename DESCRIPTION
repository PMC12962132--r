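Package: aiidval
Title: Spatial Validation of Acoustic Individual Identification Without Ground Truths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess the reliability of acoustic individual
    identification (AIID) predictions when no annotated ground truth is
    available, aimed at passive acoustic monitoring of territorial species.
    Implements locality-assumption metrics (consistency and specificity) with
    a random-prediction baseline, a label-corruption simulation that
    calibrates how well those metrics track true classifier accuracy,
    home-range agreement statistics (kernel density rasters, rank power-law
    diversity coefficients, normalised mutual information, permutation
    tests), time-difference-of-arrival multilateration with convex-hull and
    plausibility filters, and a synthetic territorial-population generator
    so the full pipeline can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
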