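#' Default pipeline configuration
#'
#' All knobs of an end-to-end run with their defaults: panel and
#' simulation settings (under `sim`), the indicator set, ST-GPR
#' hyperparameters (`stgpr`), crosswalk settings, draw count (1000)
#' and the master seed. The result of [validate_config()] on this list
#' is what [run_pipeline()] consumes.
#'
#' @param seed master integer seed.
#' @param output_dir directory for all run artifacts.
#' @return a raw configuration list (validate before use).
#' @export
default_config <- function(seed = 1L, output_dir = tempfile("anc_run_")) {
  list(
    seed = as.integer(seed),
    n_draws = 1000L,
    output_dir = output_dir,
    indicators = anc_indicator_names(),
    sim = list(),
    stgpr = list(lambda_time = 10, zeta_space = 0.3, rho = 10,
                 eta_default = 0.1, amp_factor = 2),
    crosswalk = list(trim_fraction = 0.1,
                     alternates = c("four_item_no_weight",
                                    "four_item_no_iron",
                                    "four_item_no_urine")),
    correlations = list(method = "spearman"),
    inputs = list(),
    write_draws = FALSE
  )
}

#' Validate and default a pipeline configuration
#'
#' Fills unset keys from [default_config()], rejects unknown keys
#' (reporting their paths), and checks invariants: `n_draws >= 2`,
#' indicators drawn from the nine known ones, positive ST-GPR
#' hyperparameters, referenced input paths resolvable.
#'
#' @param raw a (possibly partial) configuration list, or a path to a
#'   YAML file holding one.
#' @return a validated `anc_pipeline_config`.
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw) && length(raw) == 1L) raw <- yaml::read_yaml(raw)
  stopifnot(is.list(raw))
  def <- default_config()
  unknown <- setdiff(names(raw), names(def))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(def, raw)
  for (blk in c("stgpr", "crosswalk", "correlations")) {
    bad <- setdiff(names(cfg[[blk]]), names(def[[blk]]))
    if (length(bad)) {
      stop("unknown config key(s): ",
           paste(paste0(blk, ".", bad), collapse = ", "))
    }
  }
  if (!is.numeric(cfg$n_draws) || cfg$n_draws < 2) {
    stop("n_draws must be at least 2")
  }
  cfg$n_draws <- as.integer(cfg$n_draws)
  bad_ind <- setdiff(cfg$indicators, anc_indicator_names())
  if (length(bad_ind)) {
    stop("unknown indicator(s) in config: ", paste(bad_ind, collapse = ", "))
  }
  with(cfg$stgpr, {
    if (lambda_time <= 0 || rho <= 0 || eta_default <= 0) {
      stop("stgpr hyperparameters must be positive")
    }
    if (zeta_space < 0 || zeta_space > 1) {
      stop("stgpr.zeta_space must lie in [0, 1]")
    }
  })
  if (cfg$crosswalk$trim_fraction < 0 || cfg$crosswalk$trim_fraction >= 0.5) {
    stop("crosswalk.trim_fraction must lie in [0, 0.5)")
  }
  # sim overrides are validated by sim_config() itself
  do.call(sim_config, c(cfg$sim, list(seed = cfg$seed,
                                      indicators = cfg$indicators)))
  if (length(cfg$inputs$surveys)) {
    missing <- cfg$inputs$surveys[!file.exists(cfg$inputs$surveys)]
    if (length(missing)) {
      stop("missing survey file(s): ", paste(missing, collapse = ", "))
    }
  }
  class(cfg) <- "anc_pipeline_config"
  cfg
}

#' Run the full estimation pipeline
#'
#' Stage order: simulate (or load) microdata, tabulate every source,
#' crosswalk abbreviated composite sources, fit the three-stage model
#' per indicator, sample posterior draws, rake the content proportion
#' against its components, rescale attendee-conditional cubes by ANC1,
#' aggregate to regions and global with livebirth weights, summarise to
#' mean and 95% UI, and (if outcomes are available) correlate
#' indicators with outcomes. All value outputs are deterministic under
#' a fixed master seed: substreams are derived per stage and indicator
#' with [derive_seed()], so a rerun writes byte-identical tables.
#'
#' @param config an `anc_pipeline_config` (or a raw list/YAML path,
#'   validated on the fly).
#' @return invisibly, a run manifest list (also written as
#'   `manifest.json`) with paths, seeds, hyperparameters, per-stage row
#'   counts and timings. The summary table is at
#'   `<output_dir>/summary.csv`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (!inherits(config, "anc_pipeline_config")) config <- validate_config(config)
  t0 <- proc.time()[["elapsed"]]
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  tick <- function(name, from) {
    timings[[name]] <<- round(proc.time()[["elapsed"]] - from, 3)
  }

  # --- simulate / load inputs -------------------------------------------
  t1 <- proc.time()[["elapsed"]]
  simcfg <- do.call(sim_config, c(config$sim,
                                  list(seed = config$seed,
                                       indicators = config$indicators)))
  truth <- simulate_truth(simcfg)
  hier <- truth$hierarchy
  years <- panel_years(simcfg)
  livebirths <- simulate_livebirths(hier, years,
                                    seed = derive_seed(config$seed, 6L))
  surveys <- if (length(config$inputs$surveys)) {
    read_surveys(config$inputs$surveys)
  } else {
    simulate_surveys(truth)
  }
  outcomes <- simulate_outcomes(truth)
  anc1_cube <- simulate_anc1_draws(truth, n_draws = config$n_draws)
  write_truth(truth, file.path(out_dir, "truth.csv"))
  fwrite(truth$covariates, file.path(out_dir, "covariates.csv"))
  fwrite(livebirths, file.path(out_dir, "livebirths.csv"))
  fwrite(outcomes, file.path(out_dir, "outcomes.csv"))
  tick("simulate", t1)

  # --- tabulate ---------------------------------------------------------
  t1 <- proc.time()[["elapsed"]]
  estimates <- tabulate_sources(surveys,
                                alternates = config$crosswalk$alternates)
  if (nrow(estimates) == 0L) stop("no tabulated estimates; nothing to model")
  tick("tabulate", t1)

  # --- crosswalk --------------------------------------------------------
  t1 <- proc.time()[["elapsed"]]
  crosswalks <- list()
  full_ids <- unique(
    estimates$source_id[estimates$indicator == "anc_content_proportion" &
                          estimates$definition == "full"])
  for (alt in config$crosswalk$alternates) {
    sel_alt_only <- estimates$indicator == "anc_content_proportion" &
      estimates$definition == alt & !(estimates$source_id %in% full_ids)
    orphan <- estimates[sel_alt_only]
    if (nrow(orphan) == 0L) next
    model <- tryCatch({
      pairs <- build_pairs(estimates, alt)
      fit_crosswalk(pairs, config$crosswalk$trim_fraction, alternate = alt)
    }, anc_too_few_pairs = function(e) NULL)
    if (is.null(model)) {
      msg("no crosswalk for %s (too few pairs); %d source(s) unused",
          alt, nrow(orphan))
      next
    }
    crosswalks[[alt]] <- model
    estimates <- rbind(estimates, apply_crosswalk(orphan, model))
    write_crosswalk(model, file.path(out_dir,
                                     sprintf("crosswalk_%s.yaml", alt)))
  }
  fwrite(estimates, file.path(out_dir, "source_estimates.csv"))
  tick("crosswalk", t1)

  # --- model per indicator ----------------------------------------------
  t1 <- proc.time()[["elapsed"]]
  cubes <- list()
  etas <- list()
  for (i in seq_along(config$indicators)) {
    ind <- config$indicators[[i]]
    frame <- build_model_frame(estimates, truth$covariates, ind)
    s1 <- fit_stage1(frame)
    s2 <- smooth_residuals(frame, s1, config$stgpr$lambda_time,
                           config$stgpr$zeta_space)
    eta <- estimate_amplitude(frame, s2, default = config$stgpr$eta_default,
                              amp_factor = config$stgpr$amp_factor)
    post <- fit_gpr(s2, frame, eta, config$stgpr$rho,
                    prior_mean_var = s1$ranef_var)
    cubes[[ind]] <- sample_draws(post, config$n_draws,
                                 seed = derive_seed(config$seed, 10L + i))
    etas[[ind]] <- eta
  }
  tick("model", t1)

  # --- postprocess ------------------------------------------------------
  t1 <- proc.time()[["elapsed"]]
  # Raking happens on the attendee (conditional) scale against the four
  # attendee-conditional items; the min constraint survives the common
  # ANC1 rescaling. Iron is modelled on the all-livebirths scale, so
  # its constraint (content <= iron coverage) is applied after the
  # rescaling, where both cubes share that scale. Both minima are valid
  # in truth and jointly idempotent.
  att_items <- c("weight_measured", "bp_measured", "blood_sample",
                 "urine_sample")
  if ("anc_content_proportion" %in% names(cubes) &&
      all(att_items %in% names(cubes))) {
    cubes$anc_content_proportion <- rake_content_proportion(
      cubes$anc_content_proportion, lapply(att_items, function(x) cubes[[x]]))
  }
  scaled <- list()
  reg_tab <- anc_indicators()
  for (ind in names(cubes)) {
    cube <- cubes[[ind]]
    if (reg_tab$scale_by_anc1[match(ind, reg_tab$indicator)]) {
      cube <- scale_by_anc1(cube, anc1_cube)
    }
    scaled[[ind]] <- cube
  }
  if ("anc_content_proportion" %in% names(scaled) &&
      "iron_supplementation" %in% names(scaled)) {
    scaled$anc_content_proportion <- rake_content_proportion(
      scaled$anc_content_proportion, list(scaled$iron_supplementation))
  }
  final <- list()
  for (ind in names(scaled)) {
    final[[ind]] <- aggregate_regions(scaled[[ind]], hier, livebirths)
    if (isTRUE(config$write_draws)) {
      write_draw_cube(final[[ind]], file.path(out_dir, "draws"))
    }
  }
  summary_tab <- rbindlist(lapply(final, summarize_draws))
  setorder(summary_tab, indicator, location, year)
  fwrite(summary_tab, file.path(out_dir, "summary.csv"))
  correlations <- NULL
  if (!is.null(config$correlations)) {
    corr_cubes <- cubes[intersect(c("anc_content_mean", "anc_content_proportion"),
                                  names(cubes))]
    corr_cubes$anc1 <- anc1_cube
    correlations <- correlate_with_outcomes(
      corr_cubes, outcomes, year = max(years),
      method = config$correlations$method)
    fwrite(correlations, file.path(out_dir, "correlations.csv"))
  }
  tick("postprocess", t1)

  manifest <- list(
    seed = config$seed, n_draws = config$n_draws,
    indicators = config$indicators,
    stgpr = config$stgpr,
    eta = etas,
    n_surveys = length(surveys),
    n_source_estimates = nrow(estimates),
    n_crosswalks = length(crosswalks),
    summary_rows = nrow(summary_tab),
    paths = list(summary = file.path(out_dir, "summary.csv"),
                 estimates = file.path(out_dir, "source_estimates.csv"),
                 truth = file.path(out_dir, "truth.csv")),
    timings = timings,
    total_seconds = round(proc.time()[["elapsed"]] - t0, 3)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(manifest,
              list(summary = summary_tab, estimates = estimates,
                   cubes = final, correlations = correlations,
                   truth = truth)))
}
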