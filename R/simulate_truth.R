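#' Simulate the latent truth surface
#'
#' Generates per-(country, year) true values for every indicator. Each
#' latent series follows a logit-scale (log-scale for visit counts)
#' linear model in the three covariates plus a country random intercept,
#' a smooth temporal Gaussian-process deviation, and iid cell noise.
#'
#' Item receipt is made dependent *within woman* through a shared
#' normal compliance factor `u` with sd `compliance_sd`: given `u`, the
#' five items are independent Bernoullis with probabilities
#' `plogis(alpha_j + u)`. The per-item offsets `alpha_j` are solved
#' numerically per cell so that the item *marginals* equal the logistic
#' of the linear predictor exactly. The all-five composite truth is the
#' Gauss-Hermite integral of the product, and the content-mean truth is
#' the sum of the item marginals, so the composites are internally
#' consistent by construction (composite <= min of items; mean = sum).
#' With `compliance_sd = 0` the composite reduces to the product of the
#' marginals.
#'
#' Scales of the stored truths mirror the tabulation denominators:
#' the five item columns, the two composites and `early_anc_initiation`
#' are conditional on ANC attendance; `iron_supplementation` is the
#' all-livebirths marginal (non-attendees can receive iron outside ANC,
#' with a logit penalty); `mean_anc_visits` counts non-attendees as 0
#' visits; `anc1` is the attendance proportion itself.
#'
#' @param config an [sim_config()] object.
#' @return an `anc_truth` object: list with `table` (one row per
#'   country-year), `hierarchy`, `covariates`, `config`.
#' @export
simulate_truth <- function(config) {
  validate_sim_config(config)
  hier <- location_hierarchy(config$n_regions, config$countries_per_region)
  countries <- hierarchy_countries(hier)
  years <- panel_years(config)
  nc <- nrow(countries); ny <- length(years)
  cov <- simulate_covariates(config)
  setkey(cov, location, year)

  gh <- gauss_hermite(21L)
  beta <- config$covariate_effects
  X <- as.matrix(cov[, .(x1, x2, x3)])
  xb <- c(X %*% beta)

  series <- c(names(anc_items()), "early", "anc1")
  tab <- with_seed(derive_seed(config$seed, 1L), {
    tab <- copy(cov)
    # proportion-scale latent series: 5 items (attendee scale), early
    # initiation, ANC1 attendance
    for (s in series) {
      eta <- config$item_intercepts[[s]] + xb +
        linpred_noise(config, countries, years)
      set(tab, j = paste0("eta_", s), value = eta)
    }
    # visit counts per attendee, log scale, dampened loadings so means
    # stay in a realistic 2-10 range
    eta_v <- log(config$visits_mean) + 0.25 * xb +
      0.25 * linpred_noise(config, countries, years)
    set(tab, j = "visits_per_attendee", value = pmax(exp(eta_v), 1.05))
    tab
  })

  sigma <- config$compliance_sd
  for (s in series) {
    p <- invlogit(tab[[paste0("eta_", s)]])
    set(tab, j = if (s %in% names(anc_items())) paste0("item_", s) else s,
        value = p)
  }
  setnames(tab, c("early", "anc1"), c("early_anc_initiation", "anc1"),
           skip_absent = TRUE)

  # per-cell item offsets alpha_j matching the marginals under the
  # shared compliance factor
  alpha <- sapply(names(anc_items()), function(s) {
    solve_compliance_alpha(tab[[paste0("item_", s)]], sigma, gh)
  })
  colnames(alpha) <- paste0("alpha_", names(anc_items()))
  tab <- cbind(tab, as.data.table(alpha))

  tab[, anc_content_proportion := joint_all_items(as.matrix(.SD), sigma, gh),
      .SDcols = paste0("alpha_", names(anc_items()))]
  tab[, anc_content_mean := item_iron + item_weight + item_bp +
        item_blood + item_urine]

  # iron outside ANC: same compliance factor, shifted intercept
  tab[, iron_nonattendee := gh_marginal(alpha_iron -
        config$iron_nonattendee_shift, sigma, gh)]
  tab[, iron_supplementation := anc1 * item_iron +
        (1 - anc1) * iron_nonattendee]
  tab[, mean_anc_visits := anc1 * visits_per_attendee]
  # mirror item columns under their indicator names (attendee scale)
  tab[, `:=`(weight_measured = item_weight, bp_measured = item_bp,
             blood_sample = item_blood, urine_sample = item_urine)]
  tab[, paste0("eta_", series) := NULL]

  structure(list(table = tab[], hierarchy = hier, covariates = cov,
                 config = config),
            class = "anc_truth")
}

# country intercept + smooth temporal GP deviation + iid cell noise,
# returned in (location, year) order matching a keyed CJ panel
linpred_noise <- function(config, countries, years) {
  nc <- nrow(countries); ny <- length(years)
  ce <- rnorm(nc, 0, config$country_sd)
  dev <- sample_smooth_dev(nc, years, config$gp_amplitude,
                           config$gp_timescale)
  rep(ce, each = ny) + c(t(dev)) + rnorm(nc * ny, 0, config$residual_sd)
}

#' Solve item offsets under the compliance factor
#'
#' Finds `alpha` such that `E plogis(alpha + sigma * Z) = p` for
#' standard normal `Z`, by vectorised Newton iteration (the map is
#' smooth and strictly increasing in `alpha`).
#' @keywords internal
solve_compliance_alpha <- function(p, sigma, gh) {
  if (sigma == 0) return(qlogis(p))
  alpha <- qlogis(p)
  for (it in 1:60) {
    zs <- outer(alpha, sigma * gh$nodes, "+")
    P <- plogis(zs)
    f <- c(P %*% gh$weights) - p
    if (max(abs(f)) < 1e-13) break
    fp <- c((P * (1 - P)) %*% gh$weights)
    alpha <- alpha - f / pmax(fp, 1e-12)
  }
  alpha
}

# marginal E plogis(alpha + sigma Z)
gh_marginal <- function(alpha, sigma, gh) {
  if (sigma == 0) return(plogis(alpha))
  c(plogis(outer(alpha, sigma * gh$nodes, "+")) %*% gh$weights)
}

# joint probability all five items = 1 given shared compliance factor
joint_all_items <- function(alpha_mat, sigma, gh) {
  if (sigma == 0) {
    return(exp(rowSums(log(plogis(alpha_mat)))))
  }
  out <- numeric(nrow(alpha_mat))
  for (k in seq_along(gh$nodes)) {
    out <- out + gh$weights[k] *
      exp(rowSums(log(plogis(alpha_mat + sigma * gh$nodes[k]))))
  }
  out
}

#' Extract one indicator's truth series
#'
#' @param truth an `anc_truth`.
#' @param indicator an indicator name (see [anc_indicator_names()]).
#' @return data.table `location`, `year`, `truth` on the indicator's
#'   tabulation scale.
#' @export
truth_values <- function(truth, indicator) {
  stopifnot(inherits(truth, "anc_truth"),
            indicator %in% c(anc_indicator_names(), "anc1"))
  col <- if (indicator == "iron_supplementation") "iron_supplementation"
         else indicator
  truth$table[, .(location, year, truth = get(col))]
}

#' Write the truth surface to CSV (long format)
#' @param truth an `anc_truth`.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  cols <- c("location", "region", "year", anc_indicator_names(), "anc1",
            "visits_per_attendee")
  fwrite(truth$table[, ..cols], path)
  invisible(path)
}
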