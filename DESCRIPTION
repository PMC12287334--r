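Package: fertzone
Title: Fuzzy-Geostatistical Soil Fertility Zonation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delineates soil fertility management zones by fuzzifying twelve
    measured soil parameters (pH, ECe, organic carbon, N, P, K, S, Fe, Mn, Zn,
    B, Cu) with configurable membership functions, scoring fertility on a
    0-100 scale with a Mamdani rule base and centroid defuzzification,
    interpolating scores by ordinary kriging with weighted-least-squares
    semivariogram fitting, classifying and spatially smoothing the resulting
    zones, and validating zonation against multi-season crop yields
    (regression, Welch's ANOVA, Games-Howell). Includes a calibrated generator
    of spatially autocorrelated synthetic soil and yield datasets so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
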