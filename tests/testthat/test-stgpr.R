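test_that("stage 1 recovers known covariate coefficients", {
  cfg <- sim_config(n_regions = 4L, countries_per_region = 10L,
                    year_start = 1995L, year_end = 2023L, seed = 9L)
  cov <- simulate_covariates(cfg)
  beta <- c(0.8, 0.3, -0.2)
  set.seed(10)
  countries <- unique(cov$location)
  ce <- setNames(rnorm(length(countries), 0, 0.3), countries)
  dat <- cov[sample(.N, 400)]
  dat[, y := 0.5 + as.matrix(.SD) %*% beta + ce[location] +
        rnorm(.N, 0, 0.05), .SDcols = c("x1", "x2", "x3")]
  dat[, `:=`(v = 0.05^2, source_id = sprintf("s%d", .I))]
  frame <- structure(list(data = dat, panel = copy(cov),
                          indicator = "bp_measured", transform = "logit"),
                     class = "anc_model_frame")
  s1 <- fit_stage1(frame)
  for (j in 1:3) {
    expect_lt(abs(s1$fixef[[paste0("x", j)]] - beta[j]),
              2 * s1$fixef_se[[paste0("x", j)]])
  }
  expect_gt(s1$country_sd, 0.15)
  expect_lt(s1$country_sd, 0.5)
  expect_true(all(is.finite(s1$predictions$m1)))
})

test_that("unseen countries are predicted from fixed effects alone", {
  cfg <- tiny_config(seed = 19L)
  cov <- simulate_covariates(cfg)
  dat <- cov[location != "C06"][sample(.N, 40)]
  set.seed(2)
  dat[, y := 1 + 0.5 * x1 + rnorm(.N, 0, 0.1)]
  dat[, `:=`(v = 0.01, source_id = sprintf("s%d", .I))]
  frame <- structure(list(data = dat, panel = copy(cov),
                          indicator = "bp_measured", transform = "logit"),
                     class = "anc_model_frame")
  s1 <- fit_stage1(frame)
  pred6 <- s1$predictions[location == "C06"]
  X6 <- cbind(1, as.matrix(cov[location == "C06", .(x1, x2, x3)]))
  expect_equal(pred6$m1, c(X6 %*% s1$fixef), tolerance = 1e-10)
})

test_that("stage 1 needs enough data and enough countries", {
  cfg <- tiny_config()
  cov <- simulate_covariates(cfg)
  few <- cov[1:5]
  few[, `:=`(y = 0, v = 1, source_id = "s")]
  frame <- structure(list(data = few, panel = copy(cov),
                          indicator = "bp_measured", transform = "logit"),
                     class = "anc_model_frame")
  expect_error(fit_stage1(frame), "at least 10")
  one_c <- cov[location == "C01"]
  one_c[, `:=`(y = 0, v = 1, source_id = sprintf("s%d", seq_len(.N)))]
  frame2 <- structure(list(data = one_c, panel = copy(cov),
                           indicator = "bp_measured", transform = "logit"),
                      class = "anc_model_frame")
  expect_error(fit_stage1(frame2), "2 countries")
})

test_that("a single residual is returned in full at its own cell", {
  dat <- data.table(location = "C01", year = 2002L, y = 0.7, v = 0.01,
                    source_id = "s1", region = "R1")
  mf <- manual_frame(dat, locations = c("C01", "C02"),
                     regions = c("R1", "R2"), years = 2000:2004, m1 = 0)
  s2 <- smooth_residuals(mf$frame, mf$stage1, lambda_time = 10,
                         zeta_space = 0.3)
  expect_equal(s2$prior[location == "C01" & year == 2002]$m2, 0.7)
  # same-region borrowing scales by zeta, other region by zeta^2
  expect_equal(s2$prior[location == "C02" & year == 2002]$m2, 0.7)
})

test_that("zero spatial weight and no own data leaves the prior untouched", {
  dat <- data.table(location = "C01", year = 2002L, y = 0.7, v = 0.01,
                    source_id = "s1", region = "R1")
  mf <- manual_frame(dat, locations = c("C01", "C02"),
                     regions = c("R1", "R2"), years = 2000:2004, m1 = 0.2)
  s2 <- smooth_residuals(mf$frame, mf$stage1, lambda_time = 10,
                         zeta_space = 0)
  expect_equal(s2$prior[location == "C02"]$m2, rep(0.2, 5))
})

test_that("time-symmetric opposite residuals cancel at the midpoint", {
  dat <- data.table(location = "C01", year = c(2001L, 2003L),
                    y = c(0.5, -0.5), v = 0.01,
                    source_id = c("s1", "s2"), region = "R1")
  mf <- manual_frame(dat, locations = "C01", regions = "R1",
                     years = 2000:2004, m1 = 0)
  s2 <- smooth_residuals(mf$frame, mf$stage1, 10, 0.3)
  expect_equal(s2$prior[location == "C01" & year == 2002]$m2, 0,
               tolerance = 1e-12)
})

test_that("invalid smoothing hyperparameters are rejected", {
  dat <- data.table(location = "C01", year = 2002L, y = 0.7, v = 0.01,
                    source_id = "s1", region = "R1")
  mf <- manual_frame(dat, "C01", "R1", 2000:2004)
  expect_error(smooth_residuals(mf$frame, mf$stage1, 0, 0.3),
               "lambda_time")
  expect_error(smooth_residuals(mf$frame, mf$stage1, 10, 1.5),
               "zeta_space")
})

test_that("tricube support cuts residual influence at the bandwidth", {
  dat <- data.table(location = "C01", year = 2000L, y = 1, v = 0.01,
                    source_id = "s1", region = "R1")
  mf <- manual_frame(dat, "C01", "R1", 2000:2010)
  s2 <- smooth_residuals(mf$frame, mf$stage1, lambda_time = 5,
                         zeta_space = 0.3)
  expect_equal(s2$prior[year >= 2005]$m2, rep(0, 6))  # |dy| >= lambda
  expect_gt(s2$prior[year == 2004]$m2, 0)
})

test_that("GP posterior equals the dense closed-form oracle", {
  for (seed in 1:10) {
    inst <- random_gp_instance(seed)
    gi <- gp_instance_frame(inst$years, inst$m2, inst$years[inst$obs_idx],
                            inst$y, inst$v)
    post <- fit_gpr(gi$stage2, gi$frame, inst$eta, inst$rho)
    ref <- oracle_gp(inst$years, inst$m2, inst$eta, inst$rho,
                     inst$obs_idx, inst$y, inst$v)
    expect_lt(max(abs(post$locations[["C01"]]$mean - ref$mean)), 1e-8)
    expect_lt(max(abs(post$locations[["C01"]]$cov - ref$cov)), 1e-8)
  }
})

test_that("data-free locations keep the stage-2 mean and prior variance", {
  gi <- gp_instance_frame(2000:2009, rep(0.3, 10), integer(), numeric(),
                          numeric())
  gi$frame$data <- gi$frame$data[0]
  post <- fit_gpr(gi$stage2, gi$frame, eta = 0.4, rho = 10)
  loc <- post$locations[["C01"]]
  expect_equal(loc$mean, rep(0.3, 10))
  expect_equal(sqrt(diag(loc$cov)), rep(0.4, 10), tolerance = 1e-12)
  # with unseen_var the prior variance grows by a correlated constant
  post2 <- fit_gpr(gi$stage2, gi$frame, eta = 0.4, rho = 10,
                   unseen_var = 0.09)
  expect_equal(diag(post2$locations[["C01"]]$cov),
               rep(0.4^2 + 0.09, 10), tolerance = 1e-12)
})

test_that("a near-noiseless observation is interpolated exactly", {
  gi <- gp_instance_frame(2000:2009, rep(0, 10), 2004L, y = 0.8,
                          v = 1e-12)
  post <- fit_gpr(gi$stage2, gi$frame, eta = 0.5, rho = 10)
  expect_lt(abs(post$locations[["C01"]]$mean[5] - 0.8), 1e-6)
  # and posterior variance shrinks below the prior everywhere
  expect_true(all(diag(post$locations[["C01"]]$cov) <= 0.5^2 + 1e-12))
})

test_that("conditioning on a datum lowers the posterior sd at that year", {
  gi <- gp_instance_frame(2000:2009, rep(0, 10), c(2002L, 2007L),
                          y = c(0.5, 0.2), v = c(0.04, 0.04))
  post_full <- fit_gpr(gi$stage2, gi$frame, 0.5, 10)
  gi$frame$data <- gi$frame$data[-1]
  post_drop <- fit_gpr(gi$stage2, gi$frame, 0.5, 10)
  sd_full <- sqrt(diag(post_full$locations[["C01"]]$cov))[3]
  sd_drop <- sqrt(diag(post_drop$locations[["C01"]]$cov))[3]
  expect_lt(sd_full, sd_drop)
})

test_that("amplitude estimation is a robust floored MAD", {
  make_resid_frame <- function(r) {
    n <- length(r)
    dat <- data.table(location = "C01", year = rep(2000L, n), y = r,
                      v = 0.01, source_id = sprintf("s%d", seq_len(n)),
                      region = "R1")
    prior <- data.table(location = "C01", region = "R1", year = 2000L,
                        m1 = 0, m2 = 0)
    frame <- structure(list(data = dat, panel = prior[, .(location, region,
                                                          year)],
                            indicator = "bp_measured",
                            transform = "logit"),
                       class = "anc_model_frame")
    s2 <- structure(list(prior = prior, lambda_time = 10,
                         zeta_space = 0.3), class = "anc_stage2")
    list(frame = frame, stage2 = s2)
  }
  z <- make_resid_frame(rep(0, 20))
  expect_equal(estimate_amplitude(z$frame, z$stage2, amp_factor = 1), 0.01)
  set.seed(4)
  g <- make_resid_frame(rnorm(1e4, 0, 0.37))
  expect_lt(abs(estimate_amplitude(g$frame, g$stage2, amp_factor = 1) -
                  0.37), 0.03 * 0.37)
  # 10% gross symmetric contamination: the MAD scale inflates by the
  # closed-form factor qnorm((1 + 0.5/0.9)/2) / qnorm(0.75) ~ 1.134,
  # and no further
  r <- rnorm(1e4, 0, 0.37); r[1:500] <- 3.7; r[501:1000] <- -3.7
  h <- make_resid_frame(r)
  contaminated <- 0.37 * qnorm((1 + 0.5 / 0.9) / 2) / qnorm(0.75)
  expect_lt(abs(estimate_amplitude(h$frame, h$stage2, amp_factor = 1) -
                  contaminated), 0.03 * contaminated)
  # too few residuals: configured default
  f <- make_resid_frame(rep(0.5, 3))
  expect_equal(estimate_amplitude(f$frame, f$stage2, default = 0.123), 0.123)
  # default inflation doubles the raw scale
  expect_equal(estimate_amplitude(g$frame, g$stage2),
               2 * estimate_amplitude(g$frame, g$stage2, amp_factor = 1))
})

test_that("draw sampling is deterministic, unbiased, and degenerate-safe", {
  years <- 2000:2004
  post <- structure(list(
    locations = list(
      C01 = list(mean = qlogis(seq(0.3, 0.5, length.out = 5)),
                 cov = 0.2^2 * oracle_matern32(outer(years, years, "-"), 8)),
      C02 = list(mean = rep(qlogis(0.7), 5),
                 cov = matrix(0, 5, 5))),
    years = years, eta = 0.2, rho = 8, transform = "logit",
    indicator = "bp_measured"), class = "anc_gpr")
  cube <- sample_draws(post, n_draws = 1000, seed = 77)
  expect_s3_class(cube, "anc_draw_cube")
  expect_equal(dim(cube), c(2L, 5L, 1000L))
  expect_true(all(cube >= 0 & cube <= 1))
  # zero covariance: every draw equals the posterior mean
  expect_true(all(abs(unclass(cube)["C02", , ] - 0.7) < 1e-12))
  # MC mean matches the posterior mean on the transformed scale
  logit_draws <- qlogis(unclass(cube)["C01", , ])
  mc_err <- 4 * 0.2 / sqrt(1000)
  expect_true(all(abs(rowMeans(logit_draws) -
                        post$locations$C01$mean) < mc_err))
  cube2 <- sample_draws(post, n_draws = 1000, seed = 77)
  expect_identical(unclass(cube), unclass(cube2))
  cube3 <- sample_draws(post, n_draws = 1000, seed = 78)
  expect_false(identical(unclass(cube), unclass(cube3)))
})

test_that("model frame transforms values and variances by indicator type", {
  est <- data.table(
    source_id = c("s1", "s2"), location = "C01", year = 2005L,
    indicator = c("bp_measured", "mean_anc_visits"),
    definition = "full", value = c(0.8, 4), standard_error = c(0.02, 0.1),
    n_eff = 400, denominator = c("anc_attendees", "all_livebirths"))
  cov <- simulate_covariates(tiny_config())
  fr_p <- build_model_frame(est, cov, "bp_measured")
  expect_equal(fr_p$data$y, qlogis(0.8))
  expect_equal(fr_p$data$v, (0.02 / (0.8 * 0.2))^2)
  fr_m <- build_model_frame(est, cov, "mean_anc_visits")
  expect_equal(fr_m$data$y, log(4))
  expect_equal(fr_m$data$v, (0.1 / 4)^2)
  expect_equal(fr_m$transform, "log")
})
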