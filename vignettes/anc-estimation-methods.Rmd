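---
title: "Estimating antenatal care content and timing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating antenatal care content and timing: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Household surveys (DHS/MICS-style) ask women with a recent livebirth
what happened during their antenatal care (ANC): whether they received
iron supplementation, had their weight and blood pressure measured,
gave blood and urine samples, when the first visit happened, and how
many visits they attended. Individual surveys are sparse in time and
space, use slightly different item sets, and carry sampling and design
noise. `anctrends` turns such microdata into a complete, internally
consistent country-year panel of nine indicators with 95% uncertainty
intervals:

* five content items (iron supplementation, weight, blood pressure,
  blood sample, urine sample),
* two composites (proportion receiving *all five* items; mean number of
  items received, 0–5),
* two timing/quantity indicators (first-trimester initiation; mean
  number of ANC visits).

Because population-representative survey microdata are access
restricted, the package ships a first-class synthetic-data module with
the statistical structure the estimator assumes, so every stage is
testable end to end.

## Tabulation

Surveys ask about births in a 3–5-year recall window; the tabulator
keeps only the most recent livebirth within 24 months of the interview
(inclusive on the boundary: `interview − birth ≤ 24` months at monthly
resolution) to limit recall bias. Denominators follow extraction
practice: iron is asked of every respondent with a livebirth; the four
clinic items, both composites, and the timing of the first visit are
asked only of women who attended at least one visit; visit counts are
tabulated over all respondents with non-attendees contributing zero
visits, so the visits indicator is already on the all-livebirths scale.
"First trimester" is operationalised as a first visit in pregnancy
months 1–3 (at monthly reporting resolution this is identical to
"before month 4").

Per-source uncertainty uses effective sample sizes `n_eff = n / DEFF`
with the survey's design effect. Proportions get
`SE = sqrt(p(1−p)/n_eff)` and are clamped to
`[0.5/n_eff, 1 − 0.5/n_eff]` with the SE floored at the binomial SE of
the clamped value, so degenerate 0/1 estimates remain usable on the
logit scale. Each source is assigned the rounded weighted mean birth
year of its included births.

## Crosswalking abbreviated sources

Some sources omit an item (most commonly weight, then iron) and can
only support a four-item composite. Sources reporting *both* the full
and an abbreviated composite provide pairs
`d_i = logit(full_i) − logit(alt_i)` with combined delta-method SEs.
The offset is estimated by inverse-variance-weighted meta-analysis with
DerSimonian–Laird heterogeneity `γ²` (floored at 0) and iterative
trimming: fit, drop the `⌈0.1·n⌉` pairs with the largest standardised
residuals (exact ties drop the lowest source id first), refit until
membership stabilises. Abbreviated-only sources are then adjusted by
`logit(p) + β` with logit-scale variance inflated by `β_SE² + γ²`, so
an adjusted SE is never below the original. Only the content
*proportion* is crosswalked: a four-item sum (0–4) is not on the
five-item scale, so abbreviated sources contribute no content-mean
estimate.

## The three-stage estimator

Each indicator is modelled separately on a transformed scale: logit for
proportions, natural log for the two means (the content mean is
additionally clamped to [0, 5] after back-transform).

**Stage 1 — covariate prior.** A linear mixed model
`y ~ x1 + x2 + x3 + (1 | country)`, fitted by REML with
inverse-variance weights, where the covariates stand in for ANC4
coverage, health-worker density and the Healthcare Access and Quality
index. Predictions use the fixed effects plus the country BLUP (zero
for countries without data); a singular fit falls back to
fixed-effects-only least squares.

**Stage 2 — space-time residual smoothing.** Residuals `r = y − m1`
are averaged into every panel cell with weight
`w_time(Δyear) × w_space`, a tricube time kernel
`(1 − (|Δ|/λ)³)³` with bandwidth `λ_time = 10` years, and space
weights 1 (same country), `ζ = 0.3` (same region), `ζ²` (elsewhere).
The smoother is a degree-0 local average: simpler and stable at sparse
panel edges; cells with no within-bandwidth data keep `m1`.

**Stage 3 — GP conditioning.** Per country, a Gaussian process with
prior mean `m2` and Matérn ν = 3/2 covariance
`η² (1 + √3|Δ|/ρ) exp(−√3|Δ|/ρ)`, `ρ = 10` years, is conditioned on
that country's data with observation noise equal to each point's
sampling variance. The posterior is the standard closed form (via
Cholesky; jitter escalates from 0 through 1e−8 to 1e−4 only on
factorisation failure). 1000 draws per country-year are sampled from
the posterior and back-transformed.

### Amplitude and prior-mean variance

The kernel amplitude is a robust scale of the stage-2 residuals,
`η = amp_factor × 1.4826 × MAD(y − m2)`, floored at 0.01. The raw MAD
is measured *in-sample*, at the very country-years the stage-1 random
effects and the smoother were fitted to, and therefore understates how
far the truth wanders from the prior mean elsewhere; with a couple of
surveys per country the understatement is roughly a factor two. The
default `amp_factor = 2` is the standard ST-GPR amplitude inflation;
`amp_factor = 1` recovers the raw MAD scale.

The prior mean itself is uncertain. The pipeline adds, per country, a
fully correlated variance equal to the conditional (posterior) variance
of that country's BLUP — `country_sd²` for countries never observed —
the textbook prediction variance of a group intercept in a mixed
model. With both corrections in place the replicated calibration
experiment (`analysis/07_calibration.R`) pools 95% draw-interval
coverage of the truth at 92–94%, with observed and unobserved
countries covered at similar rates.

## Post-estimation, at draw level

All adjustments happen draw by draw, before any summarisation:

1. **Raking.** The all-five content proportion can never exceed any
   single item's coverage. Each content draw is replaced by the
   minimum of itself and the four attendee-scale item draws; after
   ANC1 rescaling the same minimum is applied against the iron cube,
   which lives on the all-livebirths scale. Both constraints hold in
   truth, the pair is idempotent, and the published cubes satisfy
   content ≤ min(all five items). Raking before rescaling is valid
   because the min-constraint is invariant under the common positive
   ANC1 factor.
2. **ANC1 rescaling.** Attendee-conditional cubes (the four clinic
   items, both composites, first-trimester initiation) are multiplied
   by the ANC1 draw cube to express them among all livebirths. Iron
   (already all-livebirths at extraction) and mean visits
   (non-attendees tabulated as zero visits) are not rescaled. ANC
   attendance is modelled upstream of this package; its draws enter as
   an input cube.
3. **Aggregation.** Regions and the global total are livebirth-weighted
   means of member-country draws, per year per draw. Aggregating draws
   and then summarising is not the same as summarising and then
   aggregating; the pipeline always aggregates first.
4. **Summaries.** Mean and empirical 2.5th/97.5th percentiles across
   draws, linear-interpolation (type 7) quantiles.

Draw-level Spearman correlations with simulated health outcomes (MMR,
NMR, SBR) support the content-versus-attendance comparison; Pearson is
available behind the same interface, and correlations are computed per
draw rather than on point estimates so the reported interval reflects
estimation uncertainty.

## The synthetic-data generator

The generator emulates what the estimator assumes about real data:

* **Latent truth.** Per item, `logit(p) = α + βᵀx + country effect +
  smooth temporal GP deviation + cell noise`, with
  `β = (0.8, 0.3, −0.2)` on three standardised covariates,
  `country_sd = 0.3`, GP amplitude 0.3 with a 10-year timescale, and
  cell noise 0.1 — trajectories that move countries by tens of
  percentage points over three decades, as observed for these
  indicators.
* **Within-woman item dependence.** A shared normal compliance factor
  `u` (sd 0.6) on the logit scale: given `u`, the five items are
  independent with probabilities `plogis(α_j + u)`, and the per-cell
  offsets `α_j` are solved (Newton, Gauss–Hermite quadrature) so the
  item *marginals* match the latent model exactly. Content shortfalls
  thus cluster within health systems and the all-five composite is a
  genuine joint quantity — the integral of the product — not the
  product of marginals (which it reduces to at `compliance_sd = 0`).
  The composite truths satisfy content ≤ min(items) and
  content-mean = Σ item marginals by construction.
* **Surveys.** Poisson survey placement (default 5 per country over
  the panel, matching ~643 sources across 131 countries), ~1000
  births per survey, a 60-month recall window so the 24-month
  restriction is a real filter, design effects Uniform(1.2, 2) applied
  through `n_eff = n/DEFF`, survey weights Uniform(0.5, 1.5),
  zero-truncated negative-binomial visit counts with mean equal to
  the cell's visits-per-attendee, and first-visit months from a
  discretised Beta(2, b) over months 1–9 with `b` solved so the
  first-trimester mass equals the cell's early-initiation truth.
  Abbreviated sources drop the weight / iron / urine column with
  probabilities 0.11 / 0.09 / 0.01 (the observed 73, 61 and 7 of 643
  sources).
* **Outcomes.** Log-scale decreasing functions of the all-women
  content mean with tunable noise, strictly positive.

What it does **not** emulate: nonresponse and selection bias,
within-country inequality, DHS recode layouts, multiple births, or
correlated item missingness; passing tests therefore demonstrate the
estimator's behaviour under its own assumptions, not robustness to
violations of them.

## Numerical choices

* Logit offsets `0.5/n_eff` guard 0/1 proportions; mean-type values are
  floored away from zero before log transform.
* GP jitter escalates 0 → 1e−8 → 1e−4 (relative to the mean kernel
  diagonal) only when Cholesky fails; draw sampling uses an eigenvalue
  square root with negative eigenvalues clipped at zero, so
  rank-deficient posteriors (near-noiseless data) sample correctly.
* Ties in crosswalk trimming break deterministically by source id;
  stage-2 data are ordered by location, year, source id.
* All randomness flows from one master seed through documented
  substreams `(seed × 1009 + offset) mod (2³¹ − 1)`, keyed per stage
  and indicator, so adding an indicator does not perturb the others
  and a rerun is byte-identical.
* Quantiles are type 7 (linear interpolation); all numeric output is
  written at full double precision.

## Problem sizes

The package's standard evaluation harness
(`recovery_experiment()`, also driven by `analysis/07_calibration.R`)
uses twenty replicate panels of 40 countries × 29 years with about two
surveys per country of ~1000 women, scoring coefficient recovery,
stage-wise RMSE against the truth, and pooled draw-interval coverage
over 23 200 country-years; the end-to-end pipeline examples use the
full 40-country panel with 1000 draws. These sizes were chosen as the
smallest panels that exhibit the sparse-data regime the estimator is
designed for.

## Known limitations

* The crosswalk is an intercept-only offset with variance inflation —
  no covariates, splines, or posterior sampling; strong dose-response
  structure between definitions would be missed.
* Hyperparameters (`λ_time`, `ζ_space`, `ρ`, `amp_factor`) are fixed
  defaults exposed in configuration, not selected by held-out
  validation.
* The stationary per-indicator amplitude cannot adapt to countries
  whose data are far more or less informative than typical; the
  BLUP-variance term corrects the largest share of this.
* Mean visits among attendees and the attendee-scale iron series are
  internal quantities; only their all-livebirths counterparts are
  published.
* Iron supplementation is not rescaled by ANC1 (it is extracted among
  all livebirths); whether that matches every published use of the
  rescaling step is configurable per indicator.
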