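#!/usr/bin/env Rscript
# Step 2 -- tabulate every survey into source estimates.
#
# Applies the 24-month most-recent-livebirth restriction, then computes
# each indicator over its extraction denominator (iron among all
# respondents with a livebirth, visit counts among all respondents,
# everything else among ANC attendees), with effective sample sizes
# n/DEFF and offset-protected standard errors. Composites are also
# tabulated under the abbreviated four-item definitions so the
# crosswalk has training pairs.

suppressMessages({library(anctrends); library(data.table)})

out <- "results/analysis"
paths <- list.files(file.path(out, "surveys"), full.names = TRUE)
surveys <- read_surveys(paths)

estimates <- tabulate_sources(surveys)
fwrite(estimates, file.path(out, "source_estimates.csv"))

message(sprintf("tabulated %d source estimates from %d surveys",
                nrow(estimates), length(surveys)))
print(estimates[, .N, by = definition])
full_comp <- estimates[indicator == "anc_content_proportion" &
                         definition == "full"]
message(sprintf("surveys with the full five-item composite: %d of %d",
                nrow(full_comp), length(surveys)))
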