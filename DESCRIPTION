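Package: gwpressure
Title: Grid-Based Groundwater Pressure Scoring and Monitoring-Well Allocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quali-quantitative assessment of anthropic and environmental
    pressures on groundwater. Tessellates a study area into fixed-size grid
    blocks (merging undersized coastal fragments into their neighbours),
    counts georeferenced pressure points from a registry of weighted layers
    in each block, scores blocks by the weighted sum of counts, bins the
    scores into pressure classes and allocates monitoring wells per class.
    Includes a synthetic spatial-data generator (study-area polygons and
    uniform or clustered point layers) so the full pipeline can be exercised
    without external GIS data, plus GeoJSON/CSV readers and writers and
    choropleth maps of the resulting pressure classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    polyclip,
    readr,
    rlang,
    sp,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
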