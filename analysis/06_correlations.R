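#!/usr/bin/env Rscript
# Step 6 -- draw-level correlation of indicators with health outcomes.
#
# For the final panel year, computes the Spearman correlation across
# countries between each indicator's draws and the simulated MMR, NMR
# and SBR, summarised over draws. The content mean is compared with
# ANC1 attendance: in the simulation outcomes are driven by content,
# so content should correlate more strongly -- the same contrast the
# content-vs-attendance argument rests on.

suppressMessages({library(anctrends); library(data.table)})

out <- "results/analysis"
cfg <- read_sim_config(file.path(out, "sim_config.yaml"))
truth <- simulate_truth(cfg)
outcomes <- fread(file.path(out, "outcomes.csv"))

cubes <- list(
  anc_content_mean = readRDS("scratch/analysis_draws/anc_content_mean.rds"),
  anc_content_proportion =
    readRDS("scratch/analysis_draws/anc_content_proportion.rds"),
  anc1 = simulate_anc1_draws(truth, n_draws = 1000L))

res <- correlate_with_outcomes(cubes, outcomes, year = cfg$year_end,
                               method = "spearman")
fwrite(res, file.path(out, "correlations.csv"))
print(res)
for (o in unique(res$outcome)) {
  cm <- res[indicator == "anc_content_mean" & outcome == o]
  a1 <- res[indicator == "anc1" & outcome == o]
  message(sprintf(
    "%s: content mean %.2f (%.2f to %.2f) vs ANC1 %.2f (%.2f to %.2f)%s",
    toupper(o), cm$mean, cm$lower, cm$upper, a1$mean, a1$lower, a1$upper,
    if (cm$mean < a1$mean) "  [content more strongly correlated]" else ""))
}
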