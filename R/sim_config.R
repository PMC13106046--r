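#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate
#' the study conditions the estimator is designed for: a multidecade
#' LMIC panel (1995-2023), roughly five surveys per country over the
#' panel, around a thousand births per survey, design effects between
#' 1.2 and 2, and abbreviated sources that omit the weight item with
#' probability 0.11, the iron item with 0.09 and the urine item with
#' 0.01 (the observed shares 73/643, 61/643 and 7/643 of sources
#' missing weight, iron and another item).
#'
#' @param n_regions number of regions.
#' @param countries_per_region countries per region.
#' @param year_start,year_end inclusive panel years.
#' @param indicators indicator identifiers (subset of
#'   [anc_indicator_names()]).
#' @param seed master integer seed.
#' @param survey_rate expected surveys per country over the panel
#'   (Poisson).
#' @param mean_sample_size expected births per survey (Poisson).
#' @param design_effect_range interval the per-survey design effect is
#'   drawn from (uniform); effective sample size is `n / DEFF`.
#' @param missingness_probs named probabilities `c(weight=, iron=,
#'   other=)` that a survey omits that item's column entirely.
#' @param covariate_effects logit-scale coefficients of the three
#'   covariates (ANC4 coverage, health-worker density, HAQ index).
#' @param country_sd sd of country random intercepts (logit scale).
#' @param residual_sd sd of iid cell-level noise in the latent truth.
#' @param gp_amplitude,gp_timescale amplitude (logit scale) and
#'   timescale (years) of the smooth temporal deviation per country.
#' @param compliance_sd sd of the per-woman logit-scale compliance
#'   factor shared by the five items; 0 makes items independent so the
#'   all-five probability is the product of the marginals.
#' @param recall_window_months how far back births are sampled relative
#'   to the interview (the tabulator later restricts to 24 months).
#' @param item_intercepts named logit intercepts of the five items
#'   (attendee scale), plus `early` (first-trimester initiation) and
#'   `anc1` (any attendance).
#' @param visits_mean mean visits per attendee at covariates 0.
#' @param visits_size negative-binomial size of the visit count.
#' @param iron_nonattendee_shift logit penalty on iron receipt for
#'   women who never attended ANC (iron can be obtained outside ANC).
#' @param anc1_draw_sd logit-scale sd of the ANC1 input draw cube
#'   around its truth.
#' @param outcome_noise_sd log-scale noise sd of the simulated health
#'   outcomes (MMR, NMR, SBR).
#' @return a validated `anc_sim_config` list.
#' @export
sim_config <- function(n_regions = 4L,
                       countries_per_region = 10L,
                       year_start = 1995L,
                       year_end = 2023L,
                       indicators = anc_indicator_names(),
                       seed = 1L,
                       survey_rate = 5,
                       mean_sample_size = 1000,
                       design_effect_range = c(1.2, 2),
                       missingness_probs = c(weight = 0.11, iron = 0.09,
                                             other = 0.01),
                       covariate_effects = c(0.8, 0.3, -0.2),
                       country_sd = 0.3,
                       residual_sd = 0.1,
                       gp_amplitude = 0.3,
                       gp_timescale = 10,
                       compliance_sd = 0.6,
                       recall_window_months = 60L,
                       item_intercepts = c(iron = 0.5, weight = 1.0,
                                           bp = 1.2, blood = 0.7,
                                           urine = 0.6, early = 0.2,
                                           anc1 = 1.8),
                       visits_mean = 4.5,
                       visits_size = 8,
                       iron_nonattendee_shift = 2,
                       anc1_draw_sd = 0.05,
                       outcome_noise_sd = 0.3) {
  cfg <- list(
    n_regions = as.integer(n_regions),
    countries_per_region = as.integer(countries_per_region),
    year_start = as.integer(year_start), year_end = as.integer(year_end),
    indicators = indicators, seed = as.integer(seed),
    survey_rate = survey_rate, mean_sample_size = mean_sample_size,
    design_effect_range = design_effect_range,
    missingness_probs = missingness_probs,
    covariate_effects = covariate_effects,
    country_sd = country_sd, residual_sd = residual_sd,
    gp_amplitude = gp_amplitude, gp_timescale = gp_timescale,
    compliance_sd = compliance_sd,
    recall_window_months = as.integer(recall_window_months),
    item_intercepts = item_intercepts,
    visits_mean = visits_mean, visits_size = visits_size,
    iron_nonattendee_shift = iron_nonattendee_shift,
    anc1_draw_sd = anc1_draw_sd,
    outcome_noise_sd = outcome_noise_sd
  )
  class(cfg) <- "anc_sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config object to validate.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "anc_sim_config"))
  with(config, {
    if (year_start >= year_end) stop("year_range start must be < end")
    if (n_regions < 1L || countries_per_region < 1L) {
      stop("need at least one region and one country per region")
    }
    if (any(missingness_probs < 0 | missingness_probs > 1)) {
      stop("missingness_probs must lie in [0, 1]")
    }
    if (!all(c("weight", "iron", "other") %in% names(missingness_probs))) {
      stop("missingness_probs needs names weight, iron, other")
    }
    pos <- c(country_sd = country_sd, residual_sd = residual_sd,
             gp_amplitude = gp_amplitude, gp_timescale = gp_timescale,
             survey_rate = survey_rate, mean_sample_size = mean_sample_size,
             visits_mean = visits_mean, visits_size = visits_size)
    # sds/amplitudes may be 0 only where a degenerate (variation-off)
    # simulation is meaningful; strictly negative is always an error
    if (any(pos < 0)) stop("negative variance/rate parameter: ",
                           paste(names(pos)[pos < 0], collapse = ", "))
    if (gp_timescale <= 0) stop("gp_timescale must be > 0")
    if (compliance_sd < 0) stop("compliance_sd must be >= 0")
    if (length(design_effect_range) != 2L ||
        any(design_effect_range <= 0) ||
        diff(design_effect_range) < 0) {
      stop("design_effect_range must be a positive non-decreasing interval")
    }
    if (!all(indicators %in% anc_indicator_names())) {
      stop("unknown indicators: ",
           paste(setdiff(indicators, anc_indicator_names()), collapse = ", "))
    }
    if (length(covariate_effects) != 3L) {
      stop("covariate_effects must have length 3")
    }
  })
  config
}

#' Read/write a simulation configuration as YAML
#' @param config an `anc_sim_config`.
#' @param path file path.
#' @return `read_sim_config` returns a validated config.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "anc_sim_config"))
  out <- unclass(config)
  # named atomic vectors serialise as YAML maps so names survive
  out$missingness_probs <- as.list(out$missingness_probs)
  out$item_intercepts <- as.list(out$item_intercepts)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$missingness_probs <- unlist(raw$missingness_probs)
  raw$item_intercepts <- unlist(raw$item_intercepts)
  raw$covariate_effects <- unlist(raw$covariate_effects)
  raw$design_effect_range <- unlist(raw$design_effect_range)
  do.call(sim_config, raw)
}

#' Panel years of a simulation configuration
#' @param config an `anc_sim_config`.
#' @return integer vector of years.
#' @export
panel_years <- function(config) seq(config$year_start, config$year_end)
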