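Package: communitygreen
Title: Community Green-Space Exposure Under Alternative Spatial Boundaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the delineation of community activity
    space changes estimated associations between green space, exercise, and
    health at the county level (the modifiable areal unit problem). Provides
    a synthetic-geography generator with planted ground truth (nested
    county/block-group/place/urban-area layers, seasonal NDVI stacks, county
    health tables), construction of six boundary schemes with metric buffers,
    maximum and time-integrated NDVI phenology metrics, zonal exposure
    extraction, and the accompanying statistical battery (Levene-gated
    pooled/Welch t tests, summary-statistic t reconstruction, correlation
    matrices, and ecological regression grids over boundary schemes and
    buffer sizes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    optparse
Config/testthat/edition: 3
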