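Package: fishvuln
Title: National Vulnerability Index for Climate-Change Impacts on Marine Fisheries
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds a national vulnerability index for climate-change impacts
    on marine capture fisheries following the IPCC exposure / sensitivity /
    adaptive-capacity framework. Exposure is the multi-model ensemble-mean
    sea surface temperature anomaly averaged over each country's exclusive
    economic zone (EEZ) for a chosen representative concentration pathway
    (RCP) and projection window relative to a 1900-1950 reference
    climatology. Sensitivity and adaptive capacity are composite indices of
    eleven socio-economic variables, min-max normalized and aggregated with
    fixed weights; vulnerability is the normalized score exposure +
    sensitivity - adaptive capacity, reported with ranks, quartiles, group
    cross-tabulations and rank correlations. A seeded synthetic-data
    generator emulates the gridded climate fields, EEZ polygons and country
    indicator tables so the whole pipeline runs and is testable without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    ggplot2
Config/testthat/edition: 3
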