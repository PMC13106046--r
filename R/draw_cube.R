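#' Draw cubes: location x year x draw arrays
#'
#' The universal currency of the post-estimation steps. A cube is a
#' 3-d numeric array with dimnames `location`, `year`, `draw`, an
#' `indicator` attribute, and a `denominator` attribute recording
#' whether values are conditional on ANC attendance
#' (`"anc_attendees"`) or on the all-livebirths scale
#' (`"all_livebirths"`).
#'
#' @param arr numeric array `n_loc x n_year x n_draw`.
#' @param indicator indicator name.
#' @param denominator `"anc_attendees"` or `"all_livebirths"`.
#' @param locations,years optional dimnames (taken from `arr` if set).
#' @return an `anc_draw_cube`.
#' @export
draw_cube <- function(arr, indicator, denominator,
                      locations = dimnames(arr)[[1]],
                      years = dimnames(arr)[[2]]) {
  stopifnot(length(dim(arr)) == 3L,
            denominator %in% c("anc_attendees", "all_livebirths"))
  dimnames(arr) <- list(location = locations, year = years,
                        draw = seq_len(dim(arr)[3]))
  structure(arr, indicator = indicator, denominator = denominator,
            class = "anc_draw_cube")
}

#' @export
print.anc_draw_cube <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<anc_draw_cube> %s [%s]: %d locations x %d years x %d draws\n",
              attr(x, "indicator"), attr(x, "denominator"),
              d[1], d[2], d[3]))
  invisible(x)
}

#' Number of draws in a cube
#' @param cube an `anc_draw_cube`.
#' @export
n_draws <- function(cube) dim(cube)[3]

#' Check two cubes share locations, years and draw count
#' @keywords internal
check_aligned <- function(a, b) {
  if (!identical(dim(a), dim(b)) ||
      !identical(dimnames(a)[1:2], dimnames(b)[1:2])) {
    stop("draw cubes are not aligned (locations/years/draws differ)")
  }
  invisible(TRUE)
}

#' Rebuild a cube with new values but the same frame
#' @keywords internal
cube_like <- function(values, template, indicator = attr(template, "indicator"),
                      denominator = attr(template, "denominator")) {
  arr <- array(values, dim = dim(template), dimnames = dimnames(template))
  draw_cube(arr, indicator, denominator)
}

#' Simulate the ANC1 (any-attendance) input draw cube
#'
#' ANC attendance is modelled upstream of this pipeline; here it enters
#' as an input cube of draws. Draws are logit-normal around the
#' attendance truth with sd `config$anc1_draw_sd`.
#'
#' @param truth an `anc_truth`.
#' @param n_draws number of draws.
#' @param config optional override config.
#' @return an `anc_draw_cube` with denominator `"all_livebirths"`.
#' @export
simulate_anc1_draws <- function(truth, n_draws = 1000L,
                                config = truth$config) {
  tab <- truth$table
  locs <- unique(tab$location)
  yrs <- sort(unique(tab$year))
  # rows vary year fastest once ordered by (location, year)
  m <- matrix(qlogis(tab[order(location, year)]$anc1),
              nrow = length(locs), ncol = length(yrs), byrow = TRUE,
              dimnames = list(sort(locs), yrs))
  with_seed(derive_seed(config$seed, 5L), {
    arr <- array(rnorm(length(m) * n_draws, mean = c(m),
                       sd = config$anc1_draw_sd),
                 dim = c(nrow(m), ncol(m), n_draws))
    draw_cube(plogis(arr), "anc1", "all_livebirths",
              locations = rownames(m), years = colnames(m))
  })
}

#' Persist / load a draw cube as CSV-per-location with a manifest
#'
#' Each location gets `<dir>/<indicator>_<location>.csv` (years x
#' draws); `<dir>/<indicator>_manifest.json` records dimensions and
#' attributes.
#'
#' @param cube an `anc_draw_cube`.
#' @param dir directory.
#' @return invisible manifest path.
#' @export
write_draw_cube <- function(cube, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ind <- attr(cube, "indicator")
  locs <- dimnames(cube)[[1]]
  for (l in locs) {
    dt <- as.data.table(cube[l, , , drop = TRUE], keep.rownames = "year")
    fwrite(dt, file.path(dir, sprintf("%s_%s.csv", ind, l)))
  }
  man <- list(indicator = ind, denominator = attr(cube, "denominator"),
              locations = locs, years = dimnames(cube)[[2]],
              n_draws = dim(cube)[3])
  mp <- file.path(dir, sprintf("%s_manifest.json", ind))
  jsonlite::write_json(man, mp, auto_unbox = TRUE)
  invisible(mp)
}

#' @rdname write_draw_cube
#' @param indicator indicator whose cube to load.
#' @export
read_draw_cube <- function(dir, indicator) {
  man <- jsonlite::read_json(file.path(dir,
           sprintf("%s_manifest.json", indicator)), simplifyVector = TRUE)
  arr <- array(NA_real_, c(length(man$locations), length(man$years),
                           man$n_draws))
  for (i in seq_along(man$locations)) {
    dt <- fread(file.path(dir, sprintf("%s_%s.csv", indicator,
                                       man$locations[i])))
    arr[i, , ] <- as.matrix(dt[, -1])
  }
  draw_cube(arr, man$indicator, man$denominator,
            locations = man$locations, years = man$years)
}
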