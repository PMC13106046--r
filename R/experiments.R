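#' Replicated truth-recovery experiment
#'
#' The package's standard evaluation harness: for each replicate seed
#' it simulates a 40-country, 29-year panel (about 2 surveys per
#' country, roughly 1000 births each), tabulates one indicator, runs
#' the three model stages, and scores stage-1 coefficient recovery,
#' logit-scale RMSE of stage 1 and of the final posterior mean against
#' the truth surface, and the empirical coverage of the central 95%
#' draw interval over all country-years.
#'
#' @param n_seeds number of replicates.
#' @param seed master seed (replicate seeds are derived from it).
#' @param indicator indicator scored (an attendee-scale item by
#'   default, whose truth is exactly the logistic of its linear
#'   predictor).
#' @param n_draws draws per replicate for the coverage score.
#' @param survey_rate,mean_sample_size forwarded to [sim_config()].
#' @param n_regions,countries_per_region panel dimensions.
#' @param stgpr list of ST-GPR hyperparameters (see
#'   [default_config()]).
#' @return data.table, one row per replicate: estimated coefficients
#'   (`b1..b3`), their standard errors (`se1..se3`), true coefficients
#'   (`beta1..beta3`), `rmse_stage1`, `rmse_stage3`, `coverage`,
#'   `n_cells`.
#' @export
recovery_experiment <- function(n_seeds = 20L, seed = 1L,
                                indicator = "bp_measured",
                                n_draws = 500L,
                                survey_rate = 2, mean_sample_size = 1000,
                                n_regions = 4L, countries_per_region = 10L,
                                stgpr = list(lambda_time = 10,
                                             zeta_space = 0.3, rho = 10,
                                             eta_default = 0.1,
                                             amp_factor = 2)) {
  rows <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    simcfg <- sim_config(n_regions = n_regions,
                         countries_per_region = countries_per_region,
                         survey_rate = survey_rate,
                         mean_sample_size = mean_sample_size,
                         seed = derive_seed(seed, 1000L + s))
    truth <- simulate_truth(simcfg)
    surveys <- simulate_surveys(truth)
    est <- tabulate_sources(surveys, indicators = indicator)
    frame <- build_model_frame(est, truth$covariates, indicator)
    s1 <- fit_stage1(frame)
    s2 <- smooth_residuals(frame, s1, stgpr$lambda_time, stgpr$zeta_space)
    eta <- estimate_amplitude(frame, s2, default = stgpr$eta_default,
                              amp_factor = stgpr$amp_factor)
    post <- fit_gpr(s2, frame, eta, stgpr$rho,
                    prior_mean_var = s1$ranef_var)
    cube <- sample_draws(post, n_draws, seed = derive_seed(seed, 2000L + s))

    tv <- truth_values(truth, indicator)
    setkey(tv, location, year)
    yrs <- post$years
    locs <- names(post$locations)
    truth_mat <- matrix(NA_real_, length(locs), length(yrs),
                        dimnames = list(locs, yrs))
    ti <- match(tv$location, locs); tj <- match(tv$year, yrs)
    truth_mat[cbind(ti, tj)] <- qlogis(tv$truth)
    m1_mat <- truth_mat; m3_mat <- truth_mat
    p1 <- s1$predictions
    m1_mat[cbind(match(p1$location, locs), match(p1$year, yrs))] <- p1$m1
    for (i in seq_along(locs)) m3_mat[i, ] <- post$locations[[i]]$mean
    rmse1 <- sqrt(mean((m1_mat - truth_mat)^2))
    rmse3 <- sqrt(mean((m3_mat - truth_mat)^2))

    lo <- apply(unclass(cube), c(1, 2), quantile, probs = 0.025,
                names = FALSE)
    hi <- apply(unclass(cube), c(1, 2), quantile, probs = 0.975,
                names = FALSE)
    truth_nat <- plogis(truth_mat)
    covered <- truth_nat >= lo & truth_nat <= hi
    rows[[s]] <- data.table(
      replicate = s,
      b1 = s1$fixef[["x1"]], b2 = s1$fixef[["x2"]], b3 = s1$fixef[["x3"]],
      se1 = s1$fixef_se[["x1"]], se2 = s1$fixef_se[["x2"]],
      se3 = s1$fixef_se[["x3"]],
      beta1 = simcfg$covariate_effects[1],
      beta2 = simcfg$covariate_effects[2],
      beta3 = simcfg$covariate_effects[3],
      rmse_stage1 = rmse1, rmse_stage3 = rmse3,
      coverage = mean(covered), n_cells = length(covered))
  }
  rbindlist(rows)
}

#' Simulate crosswalk training pairs with known offset
#'
#' Pair differences are drawn around a known logit offset `delta` with
#' sampling noise `se_pair` and between-source heterogeneity `gamma`;
#' a fraction of pairs is replaced by gross outliers at a fixed value.
#' Used to exercise the trimmed meta-regression.
#'
#' @param n_pairs number of paired sources.
#' @param delta true logit offset (full minus alternate).
#' @param se_pair per-pair sampling SE of the difference.
#' @param gamma between-source sd.
#' @param outlier_frac fraction of pairs replaced by outliers.
#' @param outlier_value the outlying difference value.
#' @param seed integer seed.
#' @return a `PairTable` (`source_id`, `d`, `se_d`).
#' @export
simulate_crosswalk_pairs <- function(n_pairs = 200L, delta = -0.5,
                                     se_pair = 0.15, gamma = 0.1,
                                     outlier_frac = 0.1,
                                     outlier_value = 3, seed = 1L) {
  with_seed(seed, {
    d <- rnorm(n_pairs, delta, sqrt(se_pair^2 + gamma^2))
    n_out <- round(outlier_frac * n_pairs)
    if (n_out > 0L) {
      out_idx <- sample.int(n_pairs, n_out)
      d[out_idx] <- outlier_value
    }
    data.table(source_id = sprintf("S%04d", seq_len(n_pairs)),
               d = d, se_d = se_pair)
  })
}
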