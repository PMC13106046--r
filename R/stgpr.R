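#' Build the model frame for one indicator
#'
#' Transforms source estimates to the modelling scale (logit for
#' proportions, natural log for means), converts standard errors to
#' transformed-scale variances by the delta method, and attaches the
#' covariates. Only full-definition (including crosswalked) rows enter.
#'
#' @param estimates `SourceEstimate` table.
#' @param covariates covariate panel from [simulate_covariates()] (or a
#'   CSV with the same columns).
#' @param indicator indicator to model.
#' @return an `anc_model_frame`: list with `data` (location, year, y,
#'   v, source_id, x1..x3, region), `panel` (full location-year grid
#'   with covariates), `indicator`, `transform`.
#' @export
build_model_frame <- function(estimates, covariates, indicator) {
  est <- as.data.table(estimates)
  cov <- as.data.table(covariates)
  reg_all <- anc_indicators()
  reg_row <- match(indicator, reg_all$indicator)
  if (is.na(reg_row)) stop("unknown indicator: ", indicator)
  reg <- reg_all[reg_row]
  sel <- est$indicator == indicator &
    est$definition %in% c("full", "full (crosswalked)")
  dat <- copy(est[sel])
  if (reg$transform == "logit") {
    dat[, `:=`(y = qlogis(value),
               v = logit_var(value, standard_error))]
  } else {
    dat[, `:=`(y = log(value), v = (standard_error / value)^2)]
  }
  dat[, v := pmax(v, 1e-8)]
  dat <- dat[, .(location, year, y, v, source_id)]
  miss_loc <- setdiff(dat$location, cov$location)
  if (length(miss_loc)) stop("data location(s) not in covariate panel: ",
                             paste(miss_loc, collapse = ", "))
  dat <- merge(dat, cov, by = c("location", "year"))
  if (!all(dat$year >= min(cov$year) & dat$year <= max(cov$year))) {
    stop("data years outside the covariate panel")
  }
  structure(list(data = dat, panel = copy(cov), indicator = indicator,
                 transform = reg$transform),
            class = "anc_model_frame")
}

#' Stage 1: linear mixed-effects prior
#'
#' Fits `y ~ x1 + x2 + x3 + (1 | location)` by REML with observations
#' weighted by inverse variance, and predicts every panel cell from the
#' fixed effects plus the country's BLUP (0 for countries without
#' data). A singular fit falls back to fixed-effects-only least
#' squares with a warning.
#'
#' @param frame an `anc_model_frame`.
#' @return an `anc_stage1` list: `fixef`, `fixef_se`, `country_sd`,
#'   `predictions` (panel with `m1`), `singular`.
#' @export
fit_stage1 <- function(frame) {
  stopifnot(inherits(frame, "anc_model_frame"))
  dat <- frame$data
  if (nrow(dat) < 10L) stop("need at least 10 data rows for stage 1")
  if (length(unique(dat$location)) < 2L) {
    stop("need data from at least 2 countries for stage 1")
  }
  singular <- FALSE
  fit <- tryCatch(
    lmer(y ~ x1 + x2 + x3 + (1 | location), data = dat,
         weights = 1 / dat$v, REML = TRUE,
         control = lmerControl(check.conv.singular = "ignore")),
    error = function(e) NULL)
  if (is.null(fit) || isSingular(fit, tol = 1e-5)) {
    singular <- TRUE
    if (!is.null(fit)) {
      warning("singular stage-1 mixed model; falling back to ",
              "fixed-effects-only regression")
    }
    lmfit <- lm(y ~ x1 + x2 + x3, data = dat, weights = 1 / dat$v)
    fe <- coef(lmfit)
    fe_se <- sqrt(diag(vcov(lmfit)))
    re <- data.table(location = character(), b = numeric(),
                     condvar = numeric())
    csd <- 0
  } else {
    fe <- fixef(fit)
    fe_se <- sqrt(diag(as.matrix(vcov(fit))))
    reobj <- ranef(fit, condVar = TRUE)$location
    re <- data.table(location = rownames(reobj),
                     b = reobj[["(Intercept)"]],
                     condvar = c(attr(reobj, "postVar")[1, 1, ]))
    csd <- sqrt(as.numeric(VarCorr(fit)$location[1]))
  }
  panel <- copy(frame$panel)
  X <- cbind(1, as.matrix(panel[, .(x1, x2, x3)]))
  panel[, m1 := c(X %*% fe)]
  panel[re, m1 := m1 + i.b, on = "location"]
  # prediction variance of the country intercept: conditional (BLUP)
  # variance for observed countries, the full random-effect variance
  # for countries never seen
  mean_var <- setNames(rep(csd^2, length(unique(panel$location))),
                       unique(panel$location))
  mean_var[re$location] <- re$condvar
  structure(list(fixef = fe, fixef_se = fe_se, country_sd = csd,
                 ranef_var = mean_var,
                 predictions = panel[, .(location, region, year, m1)],
                 singular = singular),
            class = "anc_stage1")
}

#' Stage 2: locally weighted space-time residual smoothing
#'
#' Adds to the stage-1 prediction a weighted average of the data
#' residuals `r = y - m1`, with weight
#' `w_time(dyear; lambda_time) * w_space`, where the time kernel is
#' tricube (`(1 - (|dyear|/lambda)^3)^3` inside the bandwidth, 0
#' outside) and the space weight is 1 for the same country,
#' `zeta_space` for other countries in the same region and
#' `zeta_space^2` elsewhere. Cells with zero total weight keep `m1`.
#'
#' @param frame an `anc_model_frame`.
#' @param stage1 an `anc_stage1`.
#' @param lambda_time temporal bandwidth in years (> 0).
#' @param zeta_space same-region borrowing weight in `[0, 1]`.
#' @return an `anc_stage2` list: `prior` (panel with `m1`, `m2`),
#'   `lambda_time`, `zeta_space`.
#' @export
smooth_residuals <- function(frame, stage1, lambda_time = 10,
                             zeta_space = 0.3) {
  stopifnot(inherits(frame, "anc_model_frame"),
            inherits(stage1, "anc_stage1"))
  if (lambda_time <= 0) stop("invalid hyperparameter: lambda_time must be > 0")
  if (zeta_space < 0 || zeta_space > 1) {
    stop("invalid hyperparameter: zeta_space must lie in [0, 1]")
  }
  panel <- copy(stage1$predictions)
  dat <- merge(frame$data,
               stage1$predictions[, .(location, year, m1)],
               by = c("location", "year"))
  dat[, r := y - m1]
  if (nrow(dat) == 0L) {
    panel[, m2 := m1]
    return(structure(list(prior = panel, lambda_time = lambda_time,
                          zeta_space = zeta_space), class = "anc_stage2"))
  }
  # deterministic data ordering for reproducible ties
  setorder(dat, location, year, source_id)
  locs <- unique(panel$location)
  yrs <- sort(unique(panel$year))
  loc_region <- unique(panel[, .(location, region)])
  wt_time <- outer(yrs, dat$year, function(a, b) {
    u <- abs(a - b) / lambda_time
    ifelse(u < 1, (1 - u^3)^3, 0)
  })
  panel[, m2 := m1]
  for (l in locs) {
    reg_l <- loc_region$region[loc_region$location == l]
    w_space <- ifelse(dat$location == l, 1,
                      ifelse(dat$region == reg_l, zeta_space,
                             zeta_space^2))
    W <- wt_time * rep(w_space, each = length(yrs))
    tot <- rowSums(W)
    adj <- ifelse(tot > 0, c(W %*% dat$r) / pmax(tot, 1e-300), 0)
    panel[location == l, m2 := m1 + adj[match(year, yrs)]]
  }
  structure(list(prior = panel, lambda_time = lambda_time,
                 zeta_space = zeta_space),
            class = "anc_stage2")
}

#' Estimate the GP amplitude from stage-2 residuals
#'
#' Robust scale of the remaining discrepancy between the data and the
#' stage-2 prior, `1.4826 * MAD(y - m2)`, multiplied by `amp_factor`
#' and floored at 0.01. With fewer than 5 residuals the configured
#' default is returned.
#'
#' The inflation factor is the standard ST-GPR amplitude adjustment:
#' residuals are measured in-sample, at the country-years the stage-1
#' random effects and the stage-2 smoother were themselves fitted to,
#' so their spread understates how far the truth wanders from the
#' prior mean at data-free country-years. With sparse panels (a couple
#' of surveys per country) the understatement is roughly twofold,
#' hence the default of 2; set `amp_factor = 1` for the raw MAD scale.
#'
#' @param frame an `anc_model_frame`.
#' @param stage2 an `anc_stage2`.
#' @param default amplitude used when residuals are too few.
#' @param amp_factor multiplicative inflation of the MAD scale.
#' @return scalar amplitude `eta`.
#' @export
estimate_amplitude <- function(frame, stage2, default = 0.1,
                               amp_factor = 2) {
  dat <- merge(frame$data, stage2$prior[, .(location, year, m2)],
               by = c("location", "year"))
  r <- dat$y - dat$m2
  if (length(r) < 5L) return(default)
  max(amp_factor * 1.4826 * median(abs(r - median(r))), 0.01)
}

matern32 <- function(d, rho) {
  s <- sqrt(3) * abs(d) / rho
  (1 + s) * exp(-s)
}

# Cholesky, escalating jitter 1e-8 -> 1e-4 (x10 steps) only on failure
chol_jitter <- function(K) {
  for (j in c(0, 10^seq(-8, -4))) {
    L <- tryCatch(chol(K + diag(j * mean(diag(K)) + 1e-300, nrow(K))),
                  error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  stop("covariance not positive definite after jitter escalation")
}

#' Stage 3: Gaussian-process conditioning per location
#'
#' For each country, conditions a GP with prior mean `m2` and Matern
#' nu = 3/2 covariance `eta^2 * matern(|t - t'| / rho)` on that
#' country's data, with per-point observation noise equal to the data
#' variance `v`. Countries without data return the prior mean with the
#' full prior covariance.
#'
#' @param stage2 an `anc_stage2`.
#' @param frame an `anc_model_frame`.
#' @param eta kernel amplitude (> 0), e.g. from
#'   [estimate_amplitude()].
#' @param rho kernel timescale in years (> 0).
#' @param unseen_var extra prior variance, fully correlated across
#'   years, added for locations with no data. For a country never
#'   observed, the prior mean carries the whole country random
#'   intercept as error, so the standard choice is the stage-1
#'   random-intercept variance (`country_sd^2`); the default 0 keeps
#'   the pure kernel prior.
#' @param prior_mean_var optional named per-location variance of the
#'   prior mean itself, added to the prior covariance as a fully
#'   correlated constant for every named location (the pipeline passes
#'   the stage-1 BLUP conditional variances, `country_sd^2` for unseen
#'   countries). Overrides `unseen_var` where named.
#' @return an `anc_gpr` list: per-location `mean` (years vector) and
#'   `cov` (years x years), plus `years`, `eta`, `rho`, `transform`,
#'   `indicator`.
#' @export
fit_gpr <- function(stage2, frame, eta, rho = 10, unseen_var = 0,
                    prior_mean_var = NULL) {
  stopifnot(inherits(stage2, "anc_stage2"),
            inherits(frame, "anc_model_frame"))
  if (eta <= 0 || rho <= 0) stop("kernel hyperparameters must be positive")
  prior <- stage2$prior
  yrs <- sort(unique(prior$year))
  K0 <- eta^2 * matern32(outer(yrs, yrs, "-"), rho)
  dat <- copy(frame$data)
  setorder(dat, location, year, source_id)
  locations <- list()
  for (l in unique(prior$location)) {
    m2 <- prior[location == l][order(year)]$m2
    dl <- dat[location == l]
    mv <- if (!is.null(prior_mean_var) && l %in% names(prior_mean_var)) {
      prior_mean_var[[l]]
    } else if (nrow(dl) == 0L) unseen_var else 0
    Kl <- K0 + mv
    if (nrow(dl) == 0L) {
      locations[[l]] <- list(mean = m2, cov = Kl)
      next
    }
    ti <- match(dl$year, yrs)
    Kxx <- Kl[ti, ti, drop = FALSE] + diag(dl$v, nrow(dl))
    Ksx <- Kl[, ti, drop = FALSE]
    L <- chol_jitter(Kxx)
    alpha <- backsolve(L, forwardsolve(t(L), dl$y - m2[ti]))
    V <- forwardsolve(t(L), t(Ksx))
    post_mean <- m2 + c(Ksx %*% alpha)
    post_cov <- Kl - crossprod(V)
    post_cov <- (post_cov + t(post_cov)) / 2
    locations[[l]] <- list(mean = post_mean, cov = post_cov)
  }
  structure(list(locations = locations, years = yrs, eta = eta, rho = rho,
                 transform = frame$transform, indicator = frame$indicator),
            class = "anc_gpr")
}

#' Sample posterior draws and back-transform to the natural scale
#'
#' Draws `n_draws` multivariate-normal sample paths per location from
#' the GP posterior on the transformed scale, then back-transforms
#' (inverse-logit for proportions, exp for means; the content mean is
#' additionally clamped to `[0, 5]`). Deterministic given `seed`.
#'
#' @param posterior an `anc_gpr`.
#' @param n_draws number of draws (default 1000).
#' @param seed integer seed.
#' @return an `anc_draw_cube` on the natural scale, with the
#'   indicator's tabulation denominator attached.
#' @export
sample_draws <- function(posterior, n_draws = 1000L, seed = 1L) {
  stopifnot(inherits(posterior, "anc_gpr"))
  locs <- names(posterior$locations)
  yrs <- posterior$years
  ny <- length(yrs)
  reg_all <- anc_indicators()
  den <- reg_all$denominator[match(posterior$indicator, reg_all$indicator)]
  if (is.na(den)) den <- "anc_attendees"
  if (!length(den)) den <- "anc_attendees"
  arr <- array(NA_real_, c(length(locs), ny, n_draws))
  with_seed(seed, {
    for (i in seq_along(locs)) {
      p <- posterior$locations[[i]]
      ev <- eigen(p$cov, symmetric = TRUE)
      lam <- pmax(ev$values, 0)
      if (all(lam < 1e-14)) {
        x <- matrix(p$mean, ny, n_draws)
      } else {
        A <- ev$vectors %*% (sqrt(lam) * t(ev$vectors))
        z <- matrix(rnorm(ny * n_draws), ny, n_draws)
        x <- p$mean + A %*% z
      }
      arr[i, , ] <- x
    }
  })
  nat <- if (posterior$transform == "logit") plogis(arr) else exp(arr)
  if (posterior$indicator == "anc_content_mean") {
    nat <- pmin(pmax(nat, 0), 5)
  }
  draw_cube(nat, posterior$indicator, den,
            locations = locs, years = yrs)
}
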