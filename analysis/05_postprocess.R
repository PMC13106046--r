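#!/usr/bin/env Rscript
# Step 5 -- draw-level consistency, rescaling, aggregation, summaries.
#
# Rakes the content proportion so no draw exceeds any component item
# (four attendee-scale items before ANC1 rescaling, iron on the
# all-livebirths scale after), multiplies attendee-conditional cubes by
# the ANC1 draws, aggregates countries to regions and the global total
# with livebirth weights, and writes mean / 2.5th / 97.5th percentile
# summaries. Prints the headline table: all-country content proportion,
# first-trimester initiation and mean visits in 1995 and 2023.

suppressMessages({library(anctrends); library(data.table)})

out <- "results/analysis"
cfg <- read_sim_config(file.path(out, "sim_config.yaml"))
truth <- simulate_truth(cfg)  # for the hierarchy and the ANC1 input cube
anc1 <- simulate_anc1_draws(truth, n_draws = 1000L)
lb <- fread(file.path(out, "livebirths.csv"))

cubes <- sapply(anc_indicator_names(), function(ind) {
  readRDS(sprintf("scratch/analysis_draws/%s.rds", ind))
}, simplify = FALSE)

att_items <- c("weight_measured", "bp_measured", "blood_sample",
               "urine_sample")
cubes$anc_content_proportion <- rake_content_proportion(
  cubes$anc_content_proportion, lapply(att_items, function(x) cubes[[x]]))

reg <- anc_indicators()
scaled <- sapply(names(cubes), function(ind) {
  if (reg$scale_by_anc1[match(ind, reg$indicator)]) {
    scale_by_anc1(cubes[[ind]], anc1)
  } else cubes[[ind]]
}, simplify = FALSE)
scaled$anc_content_proportion <- rake_content_proportion(
  scaled$anc_content_proportion, list(scaled$iron_supplementation))

summary_tab <- rbindlist(lapply(scaled, function(cube) {
  summarize_draws(aggregate_regions(cube, truth$hierarchy, lb))
}))
setorder(summary_tab, indicator, location, year)
fwrite(summary_tab, file.path(out, "summary.csv"))

fmt <- function(ind, yr) {
  r <- summary_tab[location == "global" & indicator == ind & year == yr]
  sprintf("%.1f (%.1f-%.1f)", 100 * r$mean, 100 * r$lower, 100 * r$upper)
}
fmt_n <- function(ind, yr) {
  r <- summary_tab[location == "global" & indicator == ind & year == yr]
  sprintf("%.1f (%.1f-%.1f)", r$mean, r$lower, r$upper)
}
message("headline estimates, all simulated countries (95% UI):")
message("  all five content items, 1995:  ",
        fmt("anc_content_proportion", 1995), "%")
message("  all five content items, 2023:  ",
        fmt("anc_content_proportion", 2023), "%")
message("  first-trimester initiation, 2023: ",
        fmt("early_anc_initiation", 2023), "%")
message("  mean ANC visits, 2023:         ",
        fmt_n("mean_anc_visits", 2023))
message(sprintf("summary table: %d rows -> %s", nrow(summary_tab),
                file.path(out, "summary.csv")))
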