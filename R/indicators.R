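#' Registry of the nine antenatal care indicators
#'
#' One row per indicator with its measurement scale, tabulation
#' denominator, the transform used for modelling, and whether final
#' estimates are rescaled by ANC attendance (ANC1) to put them on the
#' all-livebirths scale.
#'
#' Denominators follow standard survey extraction practice: iron
#' supplementation is asked of every respondent with a livebirth, the
#' four clinic services, both content composites and timing of the first
#' visit are asked only of women who attended at least one ANC visit,
#' and visit counts are tabulated over all women (non-attendees
#' contribute zero visits), so the visits indicator is already on the
#' all-livebirths scale and is not rescaled.
#'
#' @return a `data.table` with columns `indicator`, `type`
#'   (`"proportion"`/`"mean"`), `denominator`, `transform`,
#'   `scale_by_anc1`.
#' @export
anc_indicators <- function() {
  data.table(
    indicator = c("iron_supplementation", "weight_measured", "bp_measured",
                  "blood_sample", "urine_sample",
                  "anc_content_proportion", "anc_content_mean",
                  "early_anc_initiation", "mean_anc_visits"),
    type = c(rep("proportion", 6L), "mean", "proportion", "mean"),
    denominator = c("all_livebirths", rep("anc_attendees", 7L),
                    "all_livebirths"),
    transform = c(rep("logit", 6L), "log", "logit", "log"),
    scale_by_anc1 = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
}

#' @rdname anc_indicators
#' @export
anc_indicator_names <- function() anc_indicators()$indicator

#' The five content items and their microdata columns
#' @return named character vector, names are item labels.
#' @export
anc_items <- function() {
  c(iron = "iron", weight = "weight_measured", bp = "bp_measured",
    blood = "blood_sample", urine = "urine_sample")
}

#' Item set of a composite definition
#'
#' `"full"` is the five-item composite; `"four_item_no_<item>"` drops
#' the named item (abbreviated sources).
#'
#' @param definition definition name.
#' @return character vector of microdata item columns.
#' @export
definition_items <- function(definition) {
  items <- anc_items()
  if (definition %in% c("full", "full (crosswalked)")) return(unname(items))
  m <- regmatches(definition, regexec("^four_item_no_([a-z]+)$", definition))[[1]]
  if (length(m) == 2L && m[2] %in% names(items)) {
    return(unname(items[setdiff(names(items), m[2])]))
  }
  stop("unknown composite definition: ", definition)
}

is_composite <- function(indicator) {
  indicator %in% c("anc_content_proportion", "anc_content_mean")
}
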