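#!/usr/bin/env Rscript
# Generate the synthetic study inputs (country table, EEZ polygons, one
# example gridded model file) and write them under results/inputs/.
#
# The full monthly climate fields are large; downstream scripts regenerate
# them in memory from the same seed instead of reading them back, so only
# a one-year excerpt of one model is written here to document the format.

suppressPackageStartupMessages(library(fishvuln))

cfg <- synth_config(seed = 42L)
out <- "results/inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

gi <- gen_indicators(cfg)
write_country_table(gi$records, file.path(out, "countries.csv"))
utils::write.csv(gi$labels, file.path(out, "archetype_labels.csv"),
                 row.names = FALSE)
message("country table: ", nrow(gi$records), " rows, archetypes ",
        paste(names(table(gi$labels$archetype)),
              table(gi$labels$archetype), collapse = " ", sep = "="))

polys <- gen_eezs(cfg)
write_eez_geojson(polys, file.path(out, "eez.geojson"))
message("EEZ polygons: ", length(polys), " features, ",
        length(unique(vapply(polys, `[[`, "", "sovereignty"))),
        " sovereignties")

excerpt <- gen_climate(cfg, 8.5, years = c(2016, 2016))[[1]]
write_gridded_csv(excerpt, file.path(out, "model01_rcp8.5_2016_excerpt.csv"))
message("wrote a one-year model excerpt (",
        length(excerpt$year), " monthly steps) as a format example")
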