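library(data.table)

# small panel used across tests: 2 regions x 3 countries, 10 years;
# dots override any default, including the panel itself
tiny_config <- function(seed = 42L, ...) {
  args <- list(n_regions = 2L, countries_per_region = 3L,
               year_start = 2000L, year_end = 2009L, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# hand-built attendee microdata for arithmetic checks; items is a matrix
# with one row per woman and columns iron, weight, bp, blood, urine
hand_microdata <- function(items, first_visit_month = NULL,
                           attended = NULL, weights = NULL,
                           n_visits = NULL) {
  n <- nrow(items)
  if (is.null(attended)) attended <- rep(1L, n)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(first_visit_month)) {
    first_visit_month <- ifelse(attended == 1L, 2L, NA_integer_)
  }
  if (is.null(n_visits)) n_visits <- ifelse(attended == 1L, 4L, 0L)
  data.table(
    woman_id = sprintf("w%03d", seq_len(n)),
    location = "C01", survey_id = "S1",
    interview_year = 2010L, interview_month = 6L,
    birth_year = 2009L, birth_month = 6L,
    attended_anc = as.integer(attended),
    survey_weight = weights, deff = 1,
    n_visits = n_visits,
    first_visit_month = first_visit_month,
    iron = items[, 1], weight_measured = ifelse(attended, items[, 2], NA),
    bp_measured = ifelse(attended, items[, 3], NA),
    blood_sample = ifelse(attended, items[, 4], NA),
    urine_sample = ifelse(attended, items[, 5], NA)
  )
}

# minimal model frame + stage objects for exercising the model stages in
# isolation (panel of `locations` over `years`, flat stage-1 mean `m1`)
manual_frame <- function(data, locations, regions, years, m1 = 0,
                         indicator = "bp_measured", transform = "logit") {
  panel <- CJ(location = locations, year = as.integer(years), sorted = TRUE)
  panel[, region := regions[match(location, locations)]]
  panel[, `:=`(x1 = 0, x2 = 0, x3 = 0)]
  frame <- structure(list(data = as.data.table(data), panel = panel,
                          indicator = indicator, transform = transform),
                     class = "anc_model_frame")
  preds <- copy(panel)[, .(location, region, year)]
  set(preds, j = "m1", value = m1)
  s1 <- structure(list(fixef = c(`(Intercept)` = m1, x1 = 0, x2 = 0, x3 = 0),
                       fixef_se = rep(0, 4), country_sd = 0,
                       predictions = preds, singular = FALSE),
                  class = "anc_stage1")
  list(frame = frame, stage1 = s1)
}

# tiny draw cube filled from a vector/array
toy_cube <- function(values, locations = c("C01", "C02"),
                     years = 2000:2001, n_draw = 3,
                     indicator = "anc_content_proportion",
                     denominator = "anc_attendees") {
  arr <- array(values, dim = c(length(locations), length(years), n_draw))
  draw_cube(arr, indicator, denominator, locations = locations,
            years = years)
}
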