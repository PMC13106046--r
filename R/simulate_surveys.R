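#' Simulate retrospective survey microdata
#'
#' Places surveys at Poisson-sampled country-years and draws one most
#' recent livebirth per interviewed woman, dated up to
#' `recall_window_months` (default 60) before the interview so that the
#' tabulator's 24-month restriction bites. Item receipt, attendance,
#' visit counts and first-visit month are drawn from the same item-level
#' model that defines the truth surface, evaluated at the *birth-year*
#' cell. With the configured probabilities a survey omits the weight,
#' iron, or urine column entirely, emulating abbreviated sources.
#'
#' @param truth an `anc_truth` from [simulate_truth()].
#' @param config optional override config (defaults to the truth's).
#' @return list of `data.table`s, one per survey, each carrying
#'   `survey_id`, `location` and `deff` columns plus the microdata
#'   fields; surveys that sample zero women are dropped with a message.
#' @export
simulate_surveys <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "anc_truth"))
  validate_sim_config(config)
  countries <- hierarchy_countries(truth$hierarchy)$location
  years <- panel_years(config)
  tab <- truth$table
  setkey(tab, location, year)

  with_seed(derive_seed(config$seed, 3L), {
    n_sv <- rpois(length(countries), config$survey_rate)
    out <- list()
    dropped <- 0L
    for (ci in seq_along(countries)) {
      if (n_sv[ci] == 0L) next
      loc <- countries[ci]
      sv_years <- sample(years, n_sv[ci], replace = TRUE)
      for (k in seq_len(n_sv[ci])) {
        sid <- sprintf("%s_y%d_s%d", loc, sv_years[k], k)
        md <- simulate_one_survey(sid, loc, sv_years[k], tab, config, years)
        if (is.null(md)) { dropped <- dropped + 1L; next }
        out[[sid]] <- md
      }
    }
    if (dropped > 0L) msg("dropped %d empty survey(s)", dropped)
    out
  })
}

simulate_one_survey <- function(survey_id, location, survey_year, tab,
                                config, years) {
  n <- rpois(1L, config$mean_sample_size)
  if (n == 0L) return(NULL)
  deff <- runif(1L, config$design_effect_range[1], config$design_effect_range[2])
  interview_month <- sample.int(12L, n, replace = TRUE)
  months_back <- sample.int(config$recall_window_months, n, replace = TRUE)
  int_idx <- survey_year * 12L + (interview_month - 1L)
  birth_idx <- int_idx - months_back
  birth_year <- birth_idx %/% 12L
  birth_month <- birth_idx %% 12L + 1L
  # truth lookup at the birth-year cell, clamped to the panel
  cell_year <- pmin(pmax(birth_year, min(years)), max(years))
  key_dt <- data.table(location = rep(location, n), year = cell_year)
  cell <- tab[key_dt, on = c("location", "year")]

  attended <- rbinom(n, 1L, cell$anc1)
  u <- rnorm(n, 0, config$compliance_sd)
  items <- anc_items()
  md <- data.table(
    woman_id = sprintf("%s_w%05d", survey_id, seq_len(n)),
    location = location, survey_id = survey_id,
    interview_year = survey_year, interview_month = interview_month,
    birth_year = birth_year, birth_month = birth_month,
    attended_anc = attended,
    survey_weight = runif(n, 0.5, 1.5),
    deff = deff
  )
  # visit counts: zero-truncated NB with mean exactly visits_per_attendee
  nv <- integer(n)
  att <- attended == 1L
  if (any(att)) {
    mu_extra <- pmax(cell$visits_per_attendee[att] - 1, 0.05)
    nv[att] <- 1L + rnbinom(sum(att), size = config$visits_size,
                            mu = mu_extra)
  }
  md[, n_visits := nv]
  # first-visit month: discretised Beta(2, b) over months 1..9 with b
  # solved so P(month <= 3) matches the early-initiation truth
  fvm <- rep(NA_integer_, n)
  if (any(att)) {
    fvm[att] <- sample_first_visit_month(cell$early_anc_initiation[att])
  }
  md[, first_visit_month := fvm]
  for (s in names(items)) {
    a <- cell[[paste0("alpha_", s)]] + u
    if (s == "iron") {
      a <- ifelse(att, a, a - config$iron_nonattendee_shift)
      md[, (items[[s]]) := rbinom(n, 1L, plogis(a))]
    } else {
      val <- rep(NA_integer_, n)
      val[att] <- rbinom(sum(att), 1L, plogis(a[att]))
      md[, (items[[s]]) := val]
    }
  }
  # abbreviated sources: drop an item column entirely
  mp <- config$missingness_probs
  if (runif(1) < mp[["weight"]]) md[, weight_measured := NULL]
  if (runif(1) < mp[["iron"]]) md[, iron := NULL]
  if (runif(1) < mp[["other"]]) md[, urine_sample := NULL]
  md[]
}

#' Sample first-visit months from a discretised beta
#'
#' Months 1..9 get the mass of Beta(2, b) on equal ninths of (0,1); `b`
#' is solved per distinct target so that the first-trimester mass
#' `pbeta(1/3, 2, b)` equals `p_early`.
#' @param p_early vector of first-trimester probabilities in (0,1).
#' @return integer months 1..9.
#' @keywords internal
sample_first_visit_month <- function(p_early) {
  pe <- pmin(pmax(p_early, 1e-6), 1 - 1e-6)
  key <- round(pe, 10)
  uk <- unique(key)
  b <- vapply(uk, function(p) {
    uniroot(function(b) pbeta(1 / 3, 2, b) - p,
            lower = 1e-4, upper = 1e3, tol = 1e-10)$root
  }, numeric(1))
  bb <- b[match(key, uk)]
  out <- integer(length(pe))
  for (ub in unique(bb)) {
    idx <- which(bb == ub)
    pr <- diff(pbeta((0:9) / 9, 2, ub))
    out[idx] <- sample.int(9L, length(idx), replace = TRUE, prob = pr)
  }
  out
}

#' Write surveys to per-survey CSV files
#' @param surveys list from [simulate_surveys()].
#' @param dir output directory (created if needed).
#' @return invisible character vector of paths.
#' @export
write_surveys <- function(surveys, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(surveys, function(md) {
    p <- file.path(dir, paste0(md$survey_id[1], ".csv"))
    fwrite(md, p)
    p
  }, character(1))
  invisible(paths)
}

#' Read surveys written by [write_surveys()]
#' @param paths CSV paths.
#' @return list of survey `data.table`s.
#' @export
read_surveys <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing survey file(s): ", paste(missing, collapse = ", "))
  }
  out <- lapply(paths, fread)
  names(out) <- vapply(out, function(md) md$survey_id[1], character(1))
  out
}
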