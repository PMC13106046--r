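#!/usr/bin/env Rscript
# Step 3 -- crosswalk abbreviated composite sources.
#
# For each abbreviated definition, sources reporting both it and the
# full composite provide logit-scale difference pairs; a trimmed
# inverse-variance meta-analysis estimates the offset, and sources that
# reported only the abbreviated definition are adjusted onto the full
# definition with inflated variance. Only the content proportion is
# crosswalked: the four-item sum is not on the five-item scale.

suppressMessages({library(anctrends); library(data.table)})

out <- "results/analysis"
estimates <- fread(file.path(out, "source_estimates.csv"))

full_ids <- unique(estimates[indicator == "anc_content_proportion" &
                               definition == "full", source_id])
for (alt in c("four_item_no_weight", "four_item_no_iron",
              "four_item_no_urine")) {
  orphan <- estimates[indicator == "anc_content_proportion" &
                        definition == alt & !(source_id %in% full_ids)]
  if (nrow(orphan) == 0L) {
    message(alt, ": no abbreviated-only sources, nothing to adjust")
    next
  }
  pairs <- build_pairs(estimates, alt)
  fwrite(pairs, file.path(out, sprintf("crosswalk_pairs_%s.csv", alt)))
  model <- fit_crosswalk(pairs, trim_fraction = 0.1, alternate = alt)
  write_crosswalk(model, file.path(out, sprintf("crosswalk_%s.yaml", alt)))
  estimates <- rbind(estimates, apply_crosswalk(orphan, model))
  message(sprintf(
    "%s: beta = %+.3f (SE %.3f), gamma = %.3f from %d pairs; adjusted %d source(s)",
    alt, model$beta, model$beta_se, model$gamma, model$n_pairs_used,
    nrow(orphan)))
}
fwrite(estimates, file.path(out, "source_estimates_crosswalked.csv"))
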