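#!/usr/bin/env Rscript
# Step 1 -- generate the study panel.
#
# Simulates the synthetic analogue of the study conditions: 40
# countries in 4 regions over 1995-2023, about five surveys per
# country, ~1000 recent births each, design effects of 1.2-2, and
# abbreviated sources that omit the weight (11%), iron (9%) or urine
# (1%) item. Writes the ground truth, covariates, livebirth weights,
# outcomes and per-survey microdata under results/analysis/.

suppressMessages({library(anctrends); library(data.table)})

out <- "results/analysis"
dir.create(file.path(out, "surveys"), recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_regions = 4L, countries_per_region = 10L,
                  year_start = 1995L, year_end = 2023L, seed = 1L)
write_sim_config(cfg, file.path(out, "sim_config.yaml"))

truth <- simulate_truth(cfg)
write_truth(truth, file.path(out, "truth.csv"))
fwrite(truth$covariates, file.path(out, "covariates.csv"))

lb <- simulate_livebirths(truth$hierarchy, panel_years(cfg),
                          seed = derive_seed(cfg$seed, 6L))
fwrite(lb, file.path(out, "livebirths.csv"))
fwrite(simulate_outcomes(truth), file.path(out, "outcomes.csv"))

surveys <- simulate_surveys(truth)
paths <- write_surveys(surveys, file.path(out, "surveys"))

n_women <- sum(vapply(surveys, nrow, integer(1)))
missing_wt <- sum(!vapply(surveys, function(s) "weight_measured" %in% names(s), logical(1)))
missing_fe <- sum(!vapply(surveys, function(s) "iron" %in% names(s), logical(1)))
message(sprintf(
  "simulated %d surveys (%d women interviewed); %d missing the weight item, %d missing iron",
  length(surveys), n_women, missing_wt, missing_fe))
message(sprintf("truth panel: %d country-years x %d indicators",
                nrow(truth$table), length(anc_indicator_names())))
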