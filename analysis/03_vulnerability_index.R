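#!/usr/bin/env Rscript
# Index stage: assemble the indicator matrix, apply the exclusion policy,
# and compute the six vulnerability tables (three RCPs x two windows).
# Reads the E1 tables written by 02_exposure.R and the country table from
# 01_generate_inputs.R; writes results/index/.

suppressPackageStartupMessages(library(fishvuln))

out <- "results/index"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

records <- read_country_table("results/inputs/countries.csv")
e1_files <- list.files("results/exposure", pattern = "^e1_.*\\.csv$",
                       full.names = TRUE)
e1 <- setNames(lapply(e1_files, utils::read.csv),
               sub("^e1_(.*)\\.csv$", "\\1", basename(e1_files)))

study <- run_country_study(records, e1)

message("included countries: ", nrow(study$tables[[1]]),
        "; excluded: ", nrow(study$exclusions))
if (nrow(study$exclusions))
  message(paste(sprintf("  %s (%s)", study$exclusions$country,
                        study$exclusions$reason), collapse = "\n"))

utils::write.csv(study$indicators, file.path(out, "indicators.csv"),
                 row.names = FALSE)
utils::write.csv(study$exclusions, file.path(out, "exclusions.csv"),
                 row.names = FALSE)
for (lbl in names(study$tables))
  write_index_csv(study$tables[[lbl]],
                  file.path(out, paste0("index_", lbl, ".csv")))

vt <- study$tables[[study$focal]]
message("focal scenario ", study$focal, ": most vulnerable = ",
        vt$country[vt$rank == 1], ", least = ",
        vt$country[vt$rank == nrow(vt)])
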