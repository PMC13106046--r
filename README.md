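# anctrends

Estimation of antenatal care (ANC) **content** and **timing**
indicators for a multi-country panel from survey microdata.

Binary ANC coverage (any visit, four or more visits) is widely
tracked, but whether women actually *receive* recommended care during
those visits — iron supplementation, weight and blood-pressure
measurement, blood and urine samples — and whether care starts in the
first trimester, is far less systematically estimated. `anctrends`
implements the full estimation machinery for nine indicators: the five
content items, the *content proportion* (all five items received), the
*content mean* (number of items, 0–5), first-trimester initiation, and
mean number of visits. It is written for epidemiologists and health
modellers who need comparable country-year series with honest
uncertainty from sparse, heterogeneous surveys.

## What it does

For each indicator $i$, country $c$, year $t$, on a transformed scale
(logit for proportions, log for means):

1. **Tabulation** — survey microdata are restricted to the most recent
   livebirth within 24 months of interview; weighted indicator values
   use the correct denominators (iron among all livebirths, clinic
   items and composites among ANC attendees, visits among all women),
   with effective sample size $n/\mathrm{DEFF}$ and offset-protected
   standard errors.
2. **Crosswalk** — sources missing an item report a four-item
   composite; a trimmed inverse-variance meta-analysis of
   $\mathrm{logit}(\text{full}) - \mathrm{logit}(\text{alt})$ pairs
   maps them onto the five-item definition with variance inflation
   $\beta_{SE}^2 + \gamma^2$.
3. **Three-stage ST-GPR** —
   stage 1: $y = \beta_0 + \beta^\top x_{ct} + u_c + \varepsilon$,
   a REML mixed model on covariates (ANC4 coverage, health-worker
   density, HAQ index) with country intercepts;
   stage 2: tricube-in-time, region-weighted residual smoothing;
   stage 3: per-country Gaussian-process conditioning with Matérn-3/2
   kernel, data-variance observation noise, MAD-based amplitude and
   BLUP prediction variance on the prior mean. 1000 posterior draws
   per country-year.
4. **Draw-level post-processing** — the content proportion is raked so
   no draw exceeds any component item; attendee-conditional cubes are
   multiplied by ANC1 (any-attendance) draws to the all-livebirths
   scale; regions and the global total are livebirth-weighted means of
   country draws; summaries report the mean and 2.5th/97.5th
   percentiles. Draw-level Spearman correlations with health outcomes
   (MMR, NMR, SBR) support content-versus-attendance comparisons.

A first-class synthetic-data module generates truth surfaces,
covariates, outcomes and survey microdata (shared-compliance-factor
item dependence, 60-month recall, design effects, abbreviated sources)
so the whole pipeline is testable without restricted data. See the
methods vignette (`vignettes/anc-estimation-methods.Rmd`) for models,
defaults and design choices.

## Worked example

```r
library(anctrends)

cfg <- validate_config(list(
  seed = 11, n_draws = 100, output_dir = "scratch/run1",
  sim = list(n_regions = 2, countries_per_region = 3,
             year_start = 2000, year_end = 2009)))
res <- run_pipeline(cfg)

res$summary[location == "global" & indicator == "anc_content_proportion" &
              year %in% c(2000, 2009)]
#>    location  year              indicator       mean      lower      upper
#> 1:   global  2000 anc_content_proportion 0.08160508 0.07123001 0.09286984
#> 2:   global  2009 anc_content_proportion 0.33883962 0.31128584 0.36133848
```

Across the six simulated countries, the share of women with a
livebirth receiving all five content items rises from 8.2% (95% UI
7.1–9.3) in 2000 to 33.9% (31.1–36.1) in 2009 — the estimates are on
the all-livebirths scale (already multiplied by ANC1 attendance), the
interval is the 2.5th–97.5th percentile of 100 draws, and every
intermediate artifact (source estimates, crosswalk fits, manifest) is
written under `output_dir`.

The `analysis/` directory holds the same workflow as numbered
narrative drivers on a study-scale panel (40 countries, 1995–2023):
`01_simulate.R` … `05_postprocess.R` produce the headline table,
`06_correlations.R` the outcome-correlation comparison, and
`07_calibration.R` the replicated recovery/calibration experiment.
Run them in order from the repository root.

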