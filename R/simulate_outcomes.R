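#' Simulate health outcomes linked to ANC content
#'
#' Country-year maternal mortality ratio (MMR), neonatal mortality rate
#' (NMR) and stillbirth rate (SBR) generated as log-scale decreasing
#' functions of the all-women content mean (attendee-scale content mean
#' times ANC1), plus configurable log-normal noise. Outcomes are
#' strictly positive by construction.
#'
#' @param truth an `anc_truth`.
#' @param config optional override config.
#' @param noise_sd log-scale noise sd; defaults to
#'   `config$outcome_noise_sd`.
#' @return data.table `location`, `year`, `outcome`, `value` (long).
#' @export
simulate_outcomes <- function(truth, config = truth$config,
                              noise_sd = config$outcome_noise_sd) {
  stopifnot(inherits(truth, "anc_truth"))
  tab <- truth$table
  z <- tab$anc_content_mean * tab$anc1
  z <- (z - mean(z)) / max(sd(z), 1e-12)
  pars <- list(mmr = c(log(400), 0.8),
               nmr = c(log(25), 0.5),
               sbr = c(log(18), 0.5))
  with_seed(derive_seed(config$seed, 4L), {
    out <- rbindlist(lapply(names(pars), function(o) {
      p <- pars[[o]]
      data.table(location = tab$location, year = tab$year, outcome = o,
                 value = exp(p[1] - p[2] * z + rnorm(length(z), 0, noise_sd)))
    }))
    setkey(out, outcome, location, year)
    out[]
  })
}
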