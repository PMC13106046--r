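test_that("raking enforces the minimum constraint and is idempotent", {
  content <- toy_cube(0.8, n_draw = 3)
  items <- lapply(c(0.9, 0.85, 0.95, 0.9, 0.92), toy_cube, n_draw = 3)
  raked <- rake_content_proportion(content, items)
  expect_equal(unique(c(unclass(raked))), 0.8)  # unchanged: min item 0.85
  items2 <- items
  items2[[2]] <- toy_cube(0.7, n_draw = 3)
  raked2 <- rake_content_proportion(content, items2)
  expect_equal(unique(c(unclass(raked2))), 0.7)
  # violations are exactly zero afterwards, and raking twice changes
  # nothing bit-exactly
  set.seed(6)
  rc <- toy_cube(runif(12), n_draw = 3)
  ri <- lapply(1:5, function(i) toy_cube(runif(12), n_draw = 3))
  r1 <- rake_content_proportion(rc, ri)
  viol <- mapply(function(it) sum(unclass(r1) > unclass(it)), ri)
  expect_equal(sum(viol), 0)
  r2 <- rake_content_proportion(r1, ri)
  expect_identical(unclass(r1), unclass(r2))
  # misaligned cubes are refused
  bad <- toy_cube(0.5, years = 2000:2002, n_draw = 3)
  expect_error(rake_content_proportion(content, list(bad)), "aligned")
})

test_that("ANC1 rescaling multiplies draws and guards the denominator", {
  cube <- toy_cube(0.9, denominator = "anc_attendees")
  anc1 <- toy_cube(0.8, indicator = "anc1", denominator = "all_livebirths")
  out <- scale_by_anc1(cube, anc1)
  expect_equal(unique(c(unclass(out))), 0.72)
  expect_equal(attr(out, "denominator"), "all_livebirths")
  expect_error(scale_by_anc1(out, anc1), "refusing")
  ones <- toy_cube(1, indicator = "anc1", denominator = "all_livebirths")
  expect_equal(unclass(scale_by_anc1(cube, ones)), unclass(cube),
               ignore_attr = TRUE)
  # draw-level product, not product of summaries: correlated draws
  a <- toy_cube(c(rep(0.2, 4), rep(0.8, 4), rep(0.5, 4)),
                locations = "C01", years = 2000:2003, n_draw = 3,
                denominator = "anc_attendees")
  b <- toy_cube(c(rep(0.8, 4), rep(0.2, 4), rep(0.5, 4)),
                locations = "C01", years = 2000:2003, n_draw = 3,
                indicator = "anc1", denominator = "all_livebirths")
  prod_cube <- scale_by_anc1(a, b)
  mean_of_prod <- mean(unclass(prod_cube)[1, 1, ])
  prod_of_means <- mean(unclass(a)[1, 1, ]) * mean(unclass(b)[1, 1, ])
  expect_equal(mean_of_prod, mean(c(0.16, 0.16, 0.25)))
  expect_false(isTRUE(all.equal(mean_of_prod, prod_of_means)))
})

test_that("aggregation is the exact livebirth-weighted draw-level mean", {
  hier <- location_hierarchy(1L, 2L)
  lb <- data.table(location = rep(c("C01", "C02"), each = 2),
                   year = rep(2000:2001, 2),
                   livebirths = c(1, 1, 3, 3))
  cube <- draw_cube(array(rep(c(0.4, 0.8), 2 * 2), c(2, 2, 2)),
                    "bp_measured", "all_livebirths",
                    locations = c("C01", "C02"), years = 2000:2001)
  agg <- aggregate_regions(cube, hier, lb)
  expect_equal(dimnames(agg)[[1]], c("C01", "C02", "R1", "global"))
  expect_equal(c(unclass(agg)["R1", , ]), rep(0.7, 4))
  expect_equal(c(unclass(agg)["global", , ]), rep(0.7, 4))
  # equal member draws pass through unchanged
  cube_eq <- draw_cube(array(0.55, c(2, 2, 2)), "bp_measured",
                       "all_livebirths", locations = c("C01", "C02"),
                       years = 2000:2001)
  agg_eq <- aggregate_regions(cube_eq, hier, lb)
  expect_equal(c(unclass(agg_eq)["global", , ]), rep(0.55, 4))
  # missing weights are reported by country-year
  expect_error(aggregate_regions(cube, hier, lb[-1]), "C01/2000")
})

test_that("global aggregate equals the direct weighted mean to 1e-12", {
  set.seed(12)
  hier <- location_hierarchy(3L, 4L)
  countries <- hierarchy_countries(hier)$location
  years <- 2000:2004
  lb <- CJ(location = countries, year = years)
  lb[, livebirths := runif(.N, 1e4, 5e5)]
  cube <- draw_cube(array(runif(12 * 5 * 50), c(12, 5, 50)),
                    "bp_measured", "all_livebirths",
                    locations = countries, years = years)
  agg <- aggregate_regions(cube, hier, lb)
  # direct two-path check: country -> global bypassing regions
  W <- matrix(lb$livebirths[match(
    paste(rep(countries, each = 5), rep(years, 12)),
    paste(lb$location, lb$year))], 12, 5, byrow = TRUE)
  direct <- sapply(seq_along(years), function(y) {
    c(t(unclass(cube)[, y, ]) %*% (W[, y] / sum(W[, y])))
  })
  expect_lt(max(abs(t(direct) - unclass(agg)["global", , ])), 1e-12)
  # and country -> region -> global using region livebirth totals
  reg_names <- paste0("R", 1:3)
  reg_tot <- sapply(seq_along(years), function(y) {
    sapply(reg_names, function(r) {
      members <- hierarchy_countries(hier)[region == r, location]
      sum(W[match(members, countries), y])
    })
  })
  via_regions <- sapply(seq_along(years), function(y) {
    c(t(unclass(agg)[reg_names, y, ]) %*% (reg_tot[, y] / sum(reg_tot[, y])))
  })
  expect_lt(max(abs(t(via_regions) - unclass(agg)["global", , ])), 1e-12)
})

test_that("summaries use interpolated percentiles around the draw mean", {
  const <- toy_cube(0.42, n_draw = 5)
  s <- summarize_draws(const)
  expect_equal(s$mean, rep(0.42, nrow(s)))
  expect_equal(s$lower, rep(0.42, nrow(s)))
  expect_equal(s$upper, rep(0.42, nrow(s)))
  draws <- (1:1000) / 1000
  cube <- draw_cube(array(rep(draws, each = 1), c(1, 1, 1000)),
                    "bp_measured", "all_livebirths",
                    locations = "C01", years = 2000)
  s2 <- summarize_draws(cube)
  expect_equal(s2$lower, oracle_quantile(draws, 0.025), tolerance = 1e-12)
  expect_equal(s2$upper, oracle_quantile(draws, 0.975), tolerance = 1e-12)
  set.seed(3)
  rcube <- toy_cube(runif(60), n_draw = 5)
  s3 <- summarize_draws(rcube)
  expect_true(all(s3$lower <= s3$mean & s3$mean <= s3$upper))
  expect_error(summarize_draws(toy_cube(0.5, n_draw = 1)), ">= 2")
})

test_that("a noiseless monotone outcome yields perfect rank correlation", {
  locs <- sprintf("C%02d", 1:10)
  vals <- seq(0.1, 0.9, length.out = 10)
  cube <- draw_cube(array(rep(vals, 4), c(10, 1, 4)), "anc_content_mean",
                    "all_livebirths", locations = locs, years = 2005)
  oc <- data.table(location = locs, year = 2005L, outcome = "mmr",
                   value = 100 - 50 * vals)
  res <- correlate_with_outcomes(list(anc_content_mean = cube), oc, 2005)
  expect_equal(res$mean, -1)
  expect_equal(res$lower, -1)
  expect_equal(res$upper, -1)
})

test_that("an unrelated outcome gives correlations near zero", {
  set.seed(8)
  locs <- sprintf("C%03d", 1:200)
  cube <- draw_cube(array(runif(200 * 1 * 20), c(200, 1, 20)),
                    "anc_content_mean", "all_livebirths",
                    locations = locs, years = 2005)
  oc <- data.table(location = locs, year = 2005L, outcome = "mmr",
                   value = exp(rnorm(200)))
  res <- correlate_with_outcomes(list(anc_content_mean = cube), oc, 2005)
  expect_lt(abs(res$mean), 0.15)
})

test_that("the more tightly linked indicator correlates more strongly", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(100 + s)
    locs <- sprintf("C%02d", 1:30)
    signal <- runif(30)
    a <- draw_cube(array(rep(signal, 20) + rnorm(600, 0, 0.02),
                         c(30, 1, 20)), "anc_content_mean",
                   "all_livebirths", locations = locs, years = 2005)
    b <- draw_cube(array(rep(signal, 20) + rnorm(600, 0, 0.5),
                         c(30, 1, 20)), "anc1",
                   "all_livebirths", locations = locs, years = 2005)
    oc <- data.table(location = locs, year = 2005L, outcome = "nmr",
                     value = exp(1 - signal + rnorm(30, 0, 0.1)))
    res <- correlate_with_outcomes(list(a = a, b = b), oc, 2005)
    if (res[indicator == "a"]$mean < res[indicator == "b"]$mean) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 9L)
})

test_that("correlation guards: too few countries, missing year", {
  cube <- toy_cube(0.5)
  oc <- data.table(location = c("C01", "C02"), year = 2000L,
                   outcome = "mmr", value = c(1, 2))
  expect_error(correlate_with_outcomes(list(x = cube), oc, 2000),
               "at least 3")
})

test_that("draw cubes round-trip through the CSV-per-location layout", {
  set.seed(14)
  cube <- toy_cube(runif(60), n_draw = 5)
  dir <- tempfile("cube_")
  write_draw_cube(cube, dir)
  back <- read_draw_cube(dir, "anc_content_proportion")
  expect_equal(unclass(back), unclass(cube), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "denominator"), attr(cube, "denominator"))
})
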