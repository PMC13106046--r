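# Independent oracles, deliberately written with direct textbook
# formulas (dense solve(), no Cholesky reuse) so they share no code
# path with the package implementations they check.

# dense closed-form GP regression oracle
oracle_matern32 <- function(h, rho) {
  a <- sqrt(3) * abs(h) / rho
  (1 + a) * exp(-a)
}

oracle_gp <- function(years, prior_mean, eta, rho, obs_idx, y, v) {
  K <- eta^2 * oracle_matern32(outer(years, years, "-"), rho)
  Kxx <- K[obs_idx, obs_idx, drop = FALSE] + diag(v, length(obs_idx))
  Ki <- solve(Kxx)
  Ksx <- K[, obs_idx, drop = FALSE]
  list(mean = c(prior_mean + Ksx %*% Ki %*% (y - prior_mean[obs_idx])),
       cov = K - Ksx %*% Ki %*% t(Ksx))
}

# build the frame/stage2 pair fit_gpr() consumes for a single location
gp_instance_frame <- function(years, m2, obs_years, y, v,
                              location = "C01") {
  prior <- data.table(location = location, region = "R1",
                      year = as.integer(years), m1 = m2, m2 = m2)
  s2 <- structure(list(prior = prior, lambda_time = 10, zeta_space = 0.3),
                  class = "anc_stage2")
  dat <- data.table(location = location, year = as.integer(obs_years),
                    y = y, v = v,
                    source_id = sprintf("s%d", seq_along(y)),
                    region = "R1")
  frame <- structure(list(data = dat, panel = prior[, .(location, region, year)],
                          indicator = "bp_measured", transform = "logit"),
                     class = "anc_model_frame")
  list(stage2 = s2, frame = frame)
}

# one random small GP instance (<= 30 years, <= 10 observations)
random_gp_instance <- function(seed) {
  set.seed(seed)
  ny <- sample(5:30, 1)
  years <- seq(2000, by = 1, length.out = ny)
  n_obs <- sample(1:10, 1)
  obs_idx <- sample(ny, n_obs, replace = TRUE)
  list(years = years,
       m2 = rnorm(ny, 0, 0.5),
       eta = runif(1, 0.1, 1),
       rho = runif(1, 2, 20),
       obs_idx = obs_idx,
       y = rnorm(n_obs, 0, 1),
       v = runif(n_obs, 0.01, 0.5))
}

# linear-interpolation (type 7) quantile computed from first principles
oracle_quantile <- function(x, p) {
  s <- sort(unname(x))
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
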