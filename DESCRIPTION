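Package: pacarbon
Title: Carbon Stocks and Deforestation Emissions in Tropical Protected Areas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forest-carbon accounting in protected areas (PAs).
    Harmonises categorical land-cover, above- and below-ground biomass, and
    fine-resolution forest-loss rasters with PA polygons on a common planar
    grid; applies the standard PA inclusion filters (minimum area, minimum
    forest pixel count, minimum forest fraction); computes per-PA carbon
    stocks and 2000-2012 deforestation emissions with a forest-fraction
    correction multiplier and an additive relative-error budget; and
    identifies disproportionately emitting PAs by flagging studentised
    residuals of a log-log regression of emissions on initial forest area.
    A deterministic synthetic-landscape generator with analytic ground truth
    makes the whole pipeline testable without the global source datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
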