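#!/usr/bin/env Rscript
# Stage 3: per-pixel vulnerability trend and its natural-breaks classing.
#
# Refits the least-squares slope of EVI over the three epochs from the
# rasters written by stage 2, classifies the slope surface into five change
# levels by Jenks natural breaks, and checks the fitted trend signs against
# the scenario truth.

library(ecovuln)

if (!file.exists("scratch/run/evi_1996.tif"))
  stop("run analysis/02_vulnerability.R first")
dir.create("results", showWarnings = FALSE)

epochs <- c("1996", "2007", "2018")
evi <- lapply(epochs, function(e)
  read_grid(sprintf("scratch/run/evi_%s.tif", e)))
trend <- jenks_classify(fit_trend(evi))
truth_sign <- read_grid("scratch/scenario/truth_trend_sign.tif")

pos <- positive_trend_fraction(trend)
rep <- recovery_report(list(trend_sign = truth_sign,
                            towns = read.csv("results/scenario_towns.csv")),
                       trend)

write.csv(data.frame(break_value = trend$breaks),
          "results/trend_breaks.csv", row.names = FALSE)
levels <- table(grid_values(trend$classes))
write.csv(data.frame(change_level = as.integer(names(levels)),
                     cells = as.integer(levels)),
          "results/trend_levels.csv", row.names = FALSE)

cat(sprintf("Cells with increasing vulnerability: %.1f%% (prescribed %.1f%%).\n",
            100 * pos, 100 * rep$true_positive_fraction))
cat(sprintf("Per-cell sign agreement with the truth map: %.1f%%.\n",
            100 * rep$sign_agreement))
cat("Natural-break boundaries of the slope surface:",
    paste(signif(trend$breaks, 4), collapse = ", "), "\n")
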