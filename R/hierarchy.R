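#' Build a global / region / country location hierarchy
#'
#' Countries are named `C01`, `C02`, ... and nested in regions `R1`,
#' `R2`, ... under a single `global` root.
#'
#' @param n_regions number of regions.
#' @param countries_per_region countries per region.
#' @return an `anc_hierarchy`: data.table with `location_id`,
#'   `parent_id`, `level`.
#' @export
location_hierarchy <- function(n_regions, countries_per_region) {
  regions <- sprintf("R%d", seq_len(n_regions))
  countries <- sprintf("C%02d", seq_len(n_regions * countries_per_region))
  h <- rbind(
    data.table(location_id = "global", parent_id = NA_character_,
               level = "global"),
    data.table(location_id = regions, parent_id = "global",
               level = "region"),
    data.table(location_id = countries,
               parent_id = rep(regions, each = countries_per_region),
               level = "country")
  )
  setattr(h, "class", c("anc_hierarchy", class(h)))
  h[]
}

#' Countries of a hierarchy, with their region
#' @param hierarchy an `anc_hierarchy`.
#' @return data.table with `location`, `region`.
#' @export
hierarchy_countries <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "anc_hierarchy"))
  hierarchy[level == "country", .(location = location_id, region = parent_id)]
}

#' Simulate annual livebirth counts per country
#'
#' Log-normal country sizes (median about 100 000 births) with a mild
#' country-specific drift over the panel; used as aggregation weights.
#'
#' @param hierarchy an `anc_hierarchy`.
#' @param years integer vector of panel years.
#' @param seed integer seed.
#' @return data.table with `location`, `year`, `livebirths`.
#' @export
simulate_livebirths <- function(hierarchy, years, seed = 1L) {
  countries <- hierarchy_countries(hierarchy)$location
  with_seed(seed, {
    base <- exp(rnorm(length(countries), log(1e5), 0.8))
    drift <- rnorm(length(countries), 0.002, 0.006)
    out <- CJ(location = countries, year = as.integer(years),
              sorted = TRUE)
    i <- match(out$location, countries)
    out[, livebirths := base[i] * exp(drift[i] * (year - min(years)))]
    out[]
  })
}

#' Validate livebirth weights against a set of country-years
#' @keywords internal
check_livebirths <- function(livebirths, countries, years) {
  need <- CJ(location = countries, year = as.integer(years))
  miss <- need[!livebirths, on = c("location", "year")]
  if (nrow(miss)) {
    stop("missing livebirth weight for ",
         paste(sprintf("%s/%d", miss$location[1:min(5, nrow(miss))],
                       miss$year[1:min(5, nrow(miss))]), collapse = ", "),
         if (nrow(miss) > 5) sprintf(" (+%d more)", nrow(miss) - 5L) else "")
  }
  invisible(TRUE)
}
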