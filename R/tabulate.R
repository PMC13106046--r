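#' Restrict microdata to recent births
#'
#' Keeps rows whose interview-to-birth gap is at most 24 months
#' (boundary inclusive): surveys ask about births over a 3-5 year
#' recall window, but only the most recent livebirth within 2 years of
#' the interview is tabulated, to limit recall bias and cohort effects.
#' Rows with missing dates are dropped with a logged count.
#'
#' @param microdata a survey `data.table` with `interview_year`,
#'   `interview_month`, `birth_year`, `birth_month`.
#' @param max_months inclusive gap bound (default 24).
#' @return the restricted `data.table` (copy).
#' @export
restrict_births <- function(microdata, max_months = 24L) {
  md <- as.data.table(microdata)
  date_cols <- c("interview_year", "interview_month", "birth_year",
                 "birth_month")
  stopifnot(all(date_cols %in% names(md)))
  ok <- complete.cases(md[, ..date_cols])
  if (any(!ok)) {
    msg("dropping %d row(s) with missing dates", sum(!ok))
    md <- md[ok]
  }
  gap <- (md$interview_year - md$birth_year) * 12L +
    (md$interview_month - md$birth_month)
  md[gap <= max_months & gap >= 0L]
}

#' Tabulate one indicator from restricted microdata
#'
#' Survey-weighted proportion or mean over the indicator's denominator:
#' iron supplementation over all respondents with a livebirth, visit
#' counts over all respondents (non-attendees contribute 0 visits), and
#' every other indicator over women with at least one ANC visit, as
#' only attendees are asked about services received. Composites are
#' computed at the woman level: the content proportion is "all items in
#' the definition's set equal 1", the content mean is the mean item
#' sum. Standard errors use the effective sample size
#' `n_eff = n / DEFF`; proportions additionally pass through
#' [apply_variance_offset()] so 0/1 estimates stay usable on the logit
#' scale.
#'
#' @param microdata restricted microdata (see [restrict_births()]).
#' @param indicator one of [anc_indicator_names()].
#' @param definition `"full"` or an abbreviated composite definition
#'   (composites only).
#' @param deff design effect; defaults to the survey's `deff` column.
#' @return a one-row `data.table` source estimate, or `NULL` (with a
#'   message) when the denominator is empty.
#' @export
tabulate_indicator <- function(microdata, indicator, definition = "full",
                               deff = NULL) {
  md <- as.data.table(microdata)
  reg_all <- anc_indicators()
  reg_row <- match(indicator, reg_all$indicator)
  if (is.na(reg_row)) stop("unknown indicator: ", indicator)
  reg <- reg_all[reg_row]
  if (!is_composite(indicator) && definition != "full") {
    stop("alternate definitions exist only for the composites")
  }
  if (is.null(deff)) deff <- if ("deff" %in% names(md)) md$deff[1] else 1
  items <- definition_items(if (is_composite(indicator)) definition else "full")
  need <- switch(indicator,
    iron_supplementation = "iron",
    weight_measured = "weight_measured",
    bp_measured = "bp_measured",
    blood_sample = "blood_sample",
    urine_sample = "urine_sample",
    early_anc_initiation = "first_visit_month",
    mean_anc_visits = "n_visits",
    anc_content_proportion = items,
    anc_content_mean = items)
  absent <- setdiff(need, names(md))
  if (length(absent)) {
    stop(errorCondition(
      paste0("definition unavailable: ", indicator, "/", definition,
             " needs column(s) ", paste(absent, collapse = ", ")),
      class = c("anc_definition_unavailable", "error")))
  }
  den <- if (reg$denominator == "anc_attendees") md[attended_anc == 1L] else md
  if (nrow(den) == 0L) {
    msg("zero denominator for %s/%s in %s", indicator, definition,
        md$survey_id[1])
    return(NULL)
  }
  wts <- den$survey_weight
  x <- switch(indicator,
    iron_supplementation = den$iron,
    weight_measured = den$weight_measured,
    bp_measured = den$bp_measured,
    blood_sample = den$blood_sample,
    urine_sample = den$urine_sample,
    early_anc_initiation = as.integer(den$first_visit_month <= 3L),
    mean_anc_visits = den$n_visits,
    anc_content_proportion = as.integer(
      rowSums(as.matrix(den[, ..items])) == length(items)),
    anc_content_mean = rowSums(as.matrix(den[, ..items])))
  n_eff <- nrow(den) / deff
  value <- weighted.mean(x, wts)
  if (reg$type == "proportion") {
    se <- sqrt(max(value * (1 - value), 0) / n_eff)
  } else {
    se <- sqrt(weighted.mean((x - value)^2, wts)) / sqrt(n_eff)
  }
  est <- data.table(
    source_id = md$survey_id[1], location = md$location[1],
    year = as.integer(round(weighted.mean(md$birth_year, md$survey_weight))),
    indicator = indicator, definition = definition,
    value = value, standard_error = se, n_eff = n_eff,
    denominator = reg$denominator)
  if (reg$type == "proportion") est <- apply_variance_offset(est)
  else {
    # keep means strictly positive and their SE positive for log-scale
    # modelling
    est[, value := pmax(value, 0.5 / n_eff)]
    est[, standard_error := pmax(standard_error, 1e-6)]
  }
  est[]
}

#' Offset degenerate proportions away from 0 and 1
#'
#' Clamps a proportion to `[0.5/n_eff, 1 - 0.5/n_eff]` and floors the
#' standard error at the binomial SE of the clamped value, so that
#' logit transforms and logit-scale variances stay finite.
#'
#' @param estimate one-row source-estimate `data.table`.
#' @return the adjusted estimate.
#' @export
apply_variance_offset <- function(estimate) {
  est <- copy(as.data.table(estimate))
  off <- 0.5 / est$n_eff
  est[, value := pmin(pmax(value, off), 1 - off)]
  est[, standard_error := pmax(standard_error,
                               sqrt(value * (1 - value) / n_eff))]
  est[]
}

#' Tabulate every available indicator and definition for a set of surveys
#'
#' For each survey: the 24-month restriction, then every indicator
#' whose columns are present. Composites are tabulated under the full
#' definition when all five items are present, and under every
#' abbreviated definition in `alternates` whose items are present; a
#' survey missing an item column therefore yields only the matching
#' abbreviated composite, while complete surveys yield both (the pairs
#' the crosswalk trains on).
#'
#' @param surveys list of survey `data.table`s.
#' @param alternates abbreviated composite definitions to tabulate.
#' @param indicators indicators to tabulate (default all nine).
#' @return a `SourceEstimate` `data.table`, one row per
#'   source x indicator x definition.
#' @export
tabulate_sources <- function(surveys,
                             alternates = c("four_item_no_weight",
                                            "four_item_no_iron",
                                            "four_item_no_urine"),
                             indicators = anc_indicator_names()) {
  rows <- list()
  for (md in surveys) {
    r <- restrict_births(md)
    if (nrow(r) == 0L) next
    for (ind in indicators) {
      # abbreviated definitions are proportion-scale only: the content
      # mean's item sum is not comparable across item subsets, so
      # abbreviated sources contribute no content-mean estimate
      defs <- if (ind == "anc_content_proportion") c("full", alternates)
              else "full"
      for (def in defs) {
        est <- tryCatch(tabulate_indicator(r, ind, def),
                        anc_definition_unavailable = function(e) NULL)
        if (!is.null(est)) rows[[length(rows) + 1L]] <- est
      }
    }
  }
  rbindlist(rows)
}
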