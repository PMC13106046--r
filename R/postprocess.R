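#' Rake the content proportion against its five components
#'
#' Logical consistency at draw level: the probability of receiving all
#' five items can never exceed any single item's coverage, so each
#' content-proportion draw is replaced by the minimum of itself and the
#' five component draws in the same (location, year, draw) cell. Raking
#' is idempotent and happens before any rescaling or aggregation.
#'
#' @param content content-proportion `anc_draw_cube`.
#' @param items list of component item cubes on the same denominator
#'   scale (the five items, or a subset when the remaining items'
#'   constraints are applied on another scale).
#' @return the raked content cube.
#' @export
rake_content_proportion <- function(content, items) {
  stopifnot(inherits(content, "anc_draw_cube"), length(items) >= 1L)
  out <- unclass(content)
  for (it in items) {
    check_aligned(content, it)
    out <- pmin(out, unclass(it))
  }
  cube_like(out, content)
}

#' Rescale attendee-conditional draws by ANC1 attendance
#'
#' Indicators asked only of ANC attendees are conditional on
#' attendance; multiplying by the ANC1 draw in the same cell converts
#' them to the all-livebirths scale. Refuses cubes already on the
#' all-livebirths scale.
#'
#' @param cube an attendee-scale `anc_draw_cube`.
#' @param anc1 the ANC1 cube (all-livebirths scale).
#' @return the rescaled cube with denominator `"all_livebirths"`.
#' @export
scale_by_anc1 <- function(cube, anc1) {
  stopifnot(inherits(cube, "anc_draw_cube"), inherits(anc1, "anc_draw_cube"))
  if (attr(cube, "denominator") != "anc_attendees") {
    stop("refusing to rescale: cube is already on the all-livebirths scale")
  }
  check_aligned(cube, anc1)
  cube_like(unclass(cube) * unclass(anc1), cube,
            denominator = "all_livebirths")
}

#' Livebirth-weighted region and global aggregates
#'
#' Appends region and global rows to a country-level cube: for each
#' draw and year, the aggregate is the livebirth-weighted mean of the
#' member countries' draws. Aggregation is done at draw level, after
#' raking and rescaling, so interval bounds of aggregates reflect the
#' full joint uncertainty.
#'
#' @param cube a country-level `anc_draw_cube`.
#' @param hierarchy an `anc_hierarchy`.
#' @param livebirths data.table `location`, `year`, `livebirths`.
#' @return a cube over countries + regions + `global`.
#' @export
aggregate_regions <- function(cube, hierarchy, livebirths) {
  stopifnot(inherits(cube, "anc_draw_cube"),
            inherits(hierarchy, "anc_hierarchy"))
  countries <- hierarchy_countries(hierarchy)
  locs <- dimnames(cube)[[1]]
  yrs <- as.integer(dimnames(cube)[[2]])
  stopifnot(all(locs %in% countries$location))
  check_livebirths(livebirths, locs, yrs)
  lb <- as.data.table(livebirths)
  W <- matrix(0, length(locs), length(yrs),
              dimnames = list(locs, yrs))
  i <- match(lb$location, locs); j <- match(lb$year, yrs)
  ok <- !is.na(i) & !is.na(j)
  W[cbind(i[ok], j[ok])] <- lb$livebirths[ok]

  groups <- c(
    setNames(lapply(unique(countries$region), function(r) {
      countries$location[countries$region == r]
    }), unique(countries$region)),
    list(global = locs))
  nd <- dim(cube)[3]
  agg <- array(NA_real_, c(length(groups), length(yrs), nd))
  for (g in seq_along(groups)) {
    members <- intersect(groups[[g]], locs)
    wm <- W[members, , drop = FALSE]
    tot <- colSums(wm)
    if (any(tot <= 0)) stop("zero total livebirths for aggregate ",
                            names(groups)[g])
    frac <- sweep(wm, 2, tot, "/")
    sub <- unclass(cube)[members, , , drop = FALSE]
    # weighted mean over members, per year per draw
    for (yy in seq_along(yrs)) {
      sl <- matrix(sub[, yy, ], nrow = length(members))
      agg[g, yy, ] <- c(frac[, yy] %*% sl)
    }
  }
  all_arr <- array(NA_real_, c(length(locs) + length(groups), length(yrs), nd))
  all_arr[seq_along(locs), , ] <- unclass(cube)
  all_arr[length(locs) + seq_along(groups), , ] <- agg
  draw_cube(all_arr, attr(cube, "indicator"), attr(cube, "denominator"),
            locations = c(locs, names(groups)), years = yrs)
}

#' Summarise a draw cube into mean and 95% uncertainty interval
#'
#' Mean plus empirical 2.5th and 97.5th percentiles across draws per
#' (location, year), using the linear-interpolation quantile definition
#' (R type 7).
#'
#' @param cube an `anc_draw_cube` (>= 2 draws).
#' @return data.table `location`, `year`, `indicator`, `mean`,
#'   `lower`, `upper`.
#' @export
summarize_draws <- function(cube) {
  stopifnot(inherits(cube, "anc_draw_cube"), dim(cube)[3] >= 2L)
  locs <- dimnames(cube)[[1]]
  yrs <- as.integer(dimnames(cube)[[2]])
  arr <- unclass(cube)
  mean_m <- apply(arr, c(1, 2), mean)
  q <- apply(arr, c(1, 2), quantile, probs = c(0.025, 0.975),
             names = FALSE, type = 7)
  out <- CJ(location = locs, year = yrs, sorted = FALSE)
  setorder(out, location, year)
  li <- match(out$location, locs); yi <- match(out$year, yrs)
  out[, `:=`(indicator = attr(cube, "indicator"),
             mean = mean_m[cbind(li, yi)],
             lower = q[cbind(1L, li, yi)],
             upper = q[cbind(2L, li, yi)])]
  out[]
}

#' Draw-level correlation of indicators with health outcomes
#'
#' For one target year: per draw, the rank (Spearman, default) or
#' Pearson correlation across countries between the indicator draw and
#' each outcome's point value, summarised by mean and 2.5/97.5
#' percentiles over draws.
#'
#' @param cubes named list of country-level `anc_draw_cube`s.
#' @param outcomes long outcome table from [simulate_outcomes()] (or a
#'   CSV with `location`, `year`, `outcome`, `value`).
#' @param year target year.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return data.table `indicator`, `outcome`, `mean`, `lower`,
#'   `upper`.
#' @export
correlate_with_outcomes <- function(cubes, outcomes, year,
                                    method = c("spearman", "pearson")) {
  method <- match.arg(method)
  oc <- as.data.table(outcomes)
  yr_target <- as.integer(year)
  oc <- oc[oc$year == yr_target]
  rows <- list()
  for (ind in names(cubes)) {
    cube <- cubes[[ind]]
    locs <- dimnames(cube)[[1]]
    if (length(locs) < 3L) stop("need at least 3 countries for correlation")
    yi <- match(as.character(yr_target), dimnames(cube)[[2]])
    if (is.na(yi)) stop("year ", yr_target, " not in cube for ", ind)
    slice <- unclass(cube)[, yi, , drop = TRUE]  # locations x draws
    for (o in unique(oc$outcome)) {
      sel <- oc$outcome == o
      ov <- oc$value[sel][match(locs, oc$location[sel])]
      if (anyNA(ov)) stop("outcome ", o, " missing for some countries")
      r <- apply(slice, 2, function(x) cor(x, ov, method = method))
      rows[[length(rows) + 1L]] <- data.table(
        indicator = ind, outcome = o, mean = mean(r),
        lower = quantile(r, 0.025, names = FALSE),
        upper = quantile(r, 0.975, names = FALSE))
    }
  }
  rbindlist(rows)
}
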