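#!/usr/bin/env Rscript
# Reporting stage: quartile cross-tabulations by economic grouping and
# continent, the emissions-vulnerability correlation with its scatter
# export, and the per-scenario extremes. Writes results/reports/.

suppressPackageStartupMessages(library(fishvuln))

out <- "results/reports"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

records <- read_country_table("results/inputs/countries.csv")
e1_files <- list.files("results/exposure", pattern = "^e1_.*\\.csv$",
                       full.names = TRUE)
e1 <- setNames(lapply(e1_files, utils::read.csv),
               sub("^e1_(.*)\\.csv$", "\\1", basename(e1_files)))
study <- run_country_study(records, e1)
rep <- study$reports

utils::write.csv(rep$economic, file.path(out, "crosstab_economic.csv"),
                 row.names = FALSE)
utils::write.csv(rep$geographic, file.path(out, "crosstab_geographic.csv"),
                 row.names = FALSE)
utils::write.csv(study$extremes, file.path(out, "scenario_extremes.csv"),
                 row.names = FALSE)

message(sprintf("LDC-like in top half: %.1f%%; OECD-like in bottom half: %.1f%%",
                100 * rep$ldc_top_half, 100 * rep$oecd_bottom_half))

if (!is.null(rep$emissions)) {
  sc <- rep$emissions$scatter
  utils::write.csv(sc, file.path(out, "emissions_scatter.csv"),
                   row.names = FALSE)
  cr <- rep$emissions$correlation
  message(sprintf(
    "emissions vs vulnerability: Spearman rho = %.3f, r^2 = %.3f (p = %.2g, n = %d)",
    cr$spearman_rho, cr$r_squared, cr$spearman_p, cr$n))
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    p <- ggplot2::ggplot(sc, ggplot2::aes(co2_per_capita, V_N,
                                          colour = class)) +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::scale_x_log10() +
      ggplot2::scale_colour_manual(
        values = c(LDC = "firebrick", OECD = "forestgreen",
                   other = "grey55")) +
      ggplot2::labs(x = "CO2 per capita (t, log scale)",
                    y = "normalized vulnerability",
                    colour = NULL) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(out, "emissions_scatter.png"), p,
                    width = 6, height = 4, dpi = 150)
  }
}
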