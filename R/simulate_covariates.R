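#' Simulate the three model covariates
#'
#' Produces smooth country-year series standing in for ANC4 coverage
#' (`x1`), health-worker density (`x2`) and the Healthcare Access and
#' Quality index (`x3`). Each series is a country intercept plus a
#' country-specific secular trend plus a smooth temporal deviation, then
#' standardised to mean 0 / sd 1 across the whole panel. Deterministic
#' given the config seed (substream offset 2).
#'
#' @param config an [sim_config()] object.
#' @return data.table with `location`, `region`, `year`, `x1`, `x2`,
#'   `x3`.
#' @export
simulate_covariates <- function(config) {
  validate_sim_config(config)
  hier <- location_hierarchy(config$n_regions, config$countries_per_region)
  countries <- hierarchy_countries(hier)
  years <- panel_years(config)
  nc <- nrow(countries); ny <- length(years)
  tt <- (years - mean(years)) / (diff(range(years)) + 1e-9)  # ~[-0.5, 0.5]
  trend_means <- c(1, 0.6, 0.8)  # all three covariates improve over time
  with_seed(derive_seed(config$seed, 2L), {
    out <- CJ(location = countries$location, year = as.integer(years),
              sorted = TRUE)
    for (j in 1:3) {
      a <- rnorm(nc, 0, 0.8)
      s <- rnorm(nc, trend_means[j], 0.3)
      dev <- sample_smooth_dev(nc, years, amplitude = 0.3,
                               timescale = config$gp_timescale)
      x <- rep(a, each = ny) + rep(s, each = ny) * rep(tt, nc) + c(t(dev))
      x <- (x - mean(x)) / sd(x)
      set(out, j = paste0("x", j), value = x)
    }
    out[countries, region := i.region, on = "location"]
    setcolorder(out, c("location", "region", "year"))
    out[]
  })
}

#' Smooth temporal deviations for a set of countries
#'
#' One squared-exponential Gaussian-process path per country over the
#' panel years. Returns the zero matrix when `amplitude` is 0.
#'
#' @return matrix `n_countries x n_years`.
#' @keywords internal
sample_smooth_dev <- function(n_countries, years, amplitude, timescale) {
  ny <- length(years)
  if (amplitude == 0 || n_countries == 0L) {
    return(matrix(0, n_countries, ny))
  }
  d <- as.matrix(dist(years))
  K <- amplitude^2 * exp(-0.5 * (d / timescale)^2)
  L <- t(chol(K + diag(1e-9 * amplitude^2, ny)))
  Z <- matrix(rnorm(n_countries * ny), ny, n_countries)
  t(L %*% Z)
}
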