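#' Pair full and abbreviated composite estimates by source
#'
#' Sources that tabulate both the full five-item composite and a given
#' abbreviated definition provide the training pairs for the crosswalk:
#' one row per source with the logit of both values and the combined
#' standard error of the logit-scale difference.
#'
#' @param estimates `SourceEstimate` table (see [tabulate_sources()]).
#' @param alternate the abbreviated definition name.
#' @param indicator composite indicator (default content proportion).
#' @return a `PairTable` with `source_id`, `logit_full`, `logit_alt`,
#'   `d` (difference), `se_d`.
#' @export
build_pairs <- function(estimates, alternate,
                        indicator = "anc_content_proportion") {
  est <- as.data.table(estimates)
  sel_full <- est$indicator == indicator & est$definition == "full"
  sel_alt <- est$indicator == indicator & est$definition == alternate
  full <- est[sel_full]
  alt <- est[sel_alt]
  pairs <- merge(
    full[, .(source_id, logit_full = qlogis(value),
             se_full = sqrt(logit_var(value, standard_error)))],
    alt[, .(source_id, logit_alt = qlogis(value),
            se_alt = sqrt(logit_var(value, standard_error)))],
    by = "source_id")
  if (nrow(pairs) < 2L) {
    stop(errorCondition(
      sprintf("fewer than 2 full/%s pairs; crosswalk cannot be fitted",
              alternate),
      class = c("anc_too_few_pairs", "error")))
  }
  pairs[, d := logit_full - logit_alt]
  pairs[, se_d := sqrt(se_full^2 + se_alt^2)]
  setorder(pairs, source_id)
  pairs[]
}

#' Fit a trimmed, regularised meta-regression crosswalk
#'
#' Estimates the mean logit-scale offset between the full composite and
#' an abbreviated definition by inverse-variance-weighted meta-analysis
#' with DerSimonian-Laird (method-of-moments) between-source
#' heterogeneity, floored at zero, and iterative trimming: fit, drop
#' the `ceiling(trim_fraction * n)` pairs with the largest standardised
#' residuals (ties broken by lowest source_id dropped first), refit
#' until the trimmed set stabilises or 100 iterations pass.
#'
#' @param pairs a `PairTable` from [build_pairs()].
#' @param trim_fraction fraction of pairs to trim, in `[0, 0.5)`.
#' @param alternate definition name recorded on the model.
#' @return an `anc_crosswalk` list: `alternate`, `beta`, `beta_se`,
#'   `gamma`, `trim_fraction`, `n_pairs_used`, `trimmed_ids`,
#'   `converged`.
#' @export
fit_crosswalk <- function(pairs, trim_fraction = 0.1,
                          alternate = attr(pairs, "alternate", exact = TRUE)) {
  pairs <- as.data.table(pairs)
  stopifnot(trim_fraction >= 0, trim_fraction < 0.5,
            all(c("source_id", "d", "se_d") %in% names(pairs)))
  n <- nrow(pairs)
  n_trim <- ceiling(trim_fraction * n)
  if (n - n_trim < 2L) stop("fewer than 2 pairs would remain after trimming")
  keep <- rep(TRUE, n)
  converged <- FALSE
  fit <- NULL
  for (it in seq_len(100L)) {
    fit <- dl_meta(pairs$d[keep], pairs$se_d[keep])
    if (n_trim == 0L) { converged <- TRUE; break }
    z <- abs(pairs$d - fit$beta) / sqrt(pairs$se_d^2 + fit$gamma^2)
    # drop the n_trim largest standardised residuals; exact ties broken
    # by dropping the lowest source_id first
    ord <- order(-z, pairs$source_id)
    new_keep <- rep(TRUE, n)
    new_keep[ord[seq_len(n_trim)]] <- FALSE
    if (identical(new_keep, keep)) { converged <- TRUE; break }
    keep <- new_keep
  }
  if (!converged) warning("crosswalk trimming did not stabilise in 100 ",
                          "iterations; returning last fit")
  fit <- dl_meta(pairs$d[keep], pairs$se_d[keep])
  structure(list(alternate = alternate, beta = fit$beta,
                 beta_se = fit$beta_se, gamma = fit$gamma,
                 trim_fraction = trim_fraction, n_pairs_used = sum(keep),
                 trimmed_ids = pairs$source_id[!keep],
                 converged = converged),
            class = "anc_crosswalk")
}

# DerSimonian-Laird random-effects meta-analysis of differences d with
# standard errors se; gamma^2 floored at 0
dl_meta <- function(d, se) {
  w <- 1 / se^2
  beta_fe <- sum(w * d) / sum(w)
  q <- sum(w * (d - beta_fe)^2)
  k <- length(d)
  gamma2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (se^2 + gamma2)
  list(beta = sum(wr * d) / sum(wr), beta_se = sqrt(1 / sum(wr)),
       gamma = sqrt(gamma2))
}

#' @export
print.anc_crosswalk <- function(x, ...) {
  cat(sprintf(
    "<anc_crosswalk> %s: beta = %.4f (SE %.4f), gamma = %.4f, %d pairs%s\n",
    x$alternate, x$beta, x$beta_se, x$gamma, x$n_pairs_used,
    if (length(x$trimmed_ids)) sprintf(" (%d trimmed)",
                                       length(x$trimmed_ids)) else ""))
  invisible(x)
}

#' Adjust an abbreviated estimate onto the full definition
#'
#' Applies the fitted logit-scale offset and inflates the variance by
#' the offset's sampling variance plus the between-source heterogeneity
#' (`beta_se^2 + gamma^2`), delta-method back-transformed; the adjusted
#' logit-scale SE is therefore never below the original. The definition
#' is relabelled `"full (crosswalked)"`.
#'
#' @param estimate one or more `SourceEstimate` rows whose `definition`
#'   equals the model's alternate.
#' @param model an `anc_crosswalk`.
#' @return the adjusted estimate rows.
#' @export
apply_crosswalk <- function(estimate, model) {
  stopifnot(inherits(model, "anc_crosswalk"))
  est <- copy(as.data.table(estimate))
  if (any(est$definition %in% c("full", "full (crosswalked)"))) {
    stop("refusing to crosswalk an estimate already on the full definition")
  }
  if (!all(est$definition == model$alternate)) {
    stop("estimate definition does not match the model's alternate")
  }
  lv <- qlogis(est$value)
  var_l <- logit_var(est$value, est$standard_error) +
    model$beta_se^2 + model$gamma^2
  p_adj <- plogis(lv + model$beta)
  est[, value := p_adj]
  est[, standard_error := sqrt(var_l) * p_adj * (1 - p_adj)]
  est[, definition := "full (crosswalked)"]
  est[]
}

#' Serialise / load a crosswalk model as YAML
#' @param model an `anc_crosswalk`.
#' @param path file path.
#' @export
write_crosswalk <- function(model, path) {
  yaml::write_yaml(unclass(model), path, precision = 15L)
  invisible(path)
}

#' @rdname write_crosswalk
#' @export
read_crosswalk <- function(path) {
  structure(yaml::read_yaml(path), class = "anc_crosswalk")
}
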