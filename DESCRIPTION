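Package: bonetemp
Title: Colourimetric Estimation of the Heat-Exposure Temperature of Burned Bone
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the temperature that human bone was exposed
    to during burning, from calibrated colour measurements. Implements
    sRGB/CIELAB colour conversion, 24-patch colour-chart calibration,
    region-of-interest measurement of scanned bone fragments with exclusion of
    a configurable outer rim, a seven-cluster L*/B* threshold decision model
    that maps a colour measurement to an exposure-temperature range and
    heat-induced-change stage, per-pixel cluster heat maps, the supporting
    correlation and standardized multiple-regression statistics, validation
    scoring, and a synthetic-data generator emulating the temperature by
    duration by medium design of heated-bone learning sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
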