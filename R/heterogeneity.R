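#' Class-balance survivorship metrics for one explant
#'
#' Known seeding density plus per-cell quantitation make a "class balance"
#' fold change possible: the scored-comet count under each condition,
#' relative to vehicle, proxies cell survivorship through repair blockade
#' and genomic assault, and flags hyper-resistant subpopulations that an
#' explant-average capacity score would mask.
#'
#' @param seeded Cells seeded per condition (> 0).
#' @param scored_counts Numeric vector `c(n1, n2, n3, n4)` of scored
#'   events per condition (vehicle, blockade, assault, both).
#' @param tails_assault Tail %DNA values under the assault condition
#'   (condition 3), used for the intra-explant extent-of-variance.
#' @return Object of class `class_balance`: survivorship fractions
#'   `S1..S4` (clipped to \[0, 1\]), fold changes `cb_blockade`,
#'   `cb_assault`, `cb_both` (each `S_c / S1`), and `extent_of_variance`
#'   (IQR of assault tails; variance and MAD are carried as evidence).
#' @export
class_balance <- function(seeded, scored_counts, tails_assault = numeric(0)) {
  if (!is.numeric(seeded) || seeded <= 0) {
    stop_ddr("seeded count must be positive", class = "ddr_schema_error")
  }
  if (length(scored_counts) != 4 || any(scored_counts < 0)) {
    stop_ddr("scored_counts must be four non-negative counts", class = "ddr_schema_error")
  }
  if (scored_counts[1] == 0) {
    stop_ddr("baseline condition has zero scored events: class balance undefined",
             class = "ddr_undefined_baseline_error")
  }
  S <- clamp(scored_counts / seeded, 0, 1)
  structure(list(
    seeded = seeded,
    scored_counts = scored_counts,
    survivorship = S,
    cb_blockade = S[2] / S[1],
    cb_assault = S[3] / S[1],
    cb_both = S[4] / S[1],
    extent_of_variance = if (length(tails_assault)) stats::IQR(tails_assault) else NA_real_,
    evidence = list(
      assault_tail_var = if (length(tails_assault)) stats::var(tails_assault) else NA_real_,
      assault_tail_mad = if (length(tails_assault)) stats::mad(tails_assault) else NA_real_,
      variance_statistic = "IQR")
  ), class = "class_balance")
}

#' @export
print.class_balance <- function(x, ...) {
  cat(sprintf("<class_balance> cb blockade %.2f, assault %.2f, both %.2f; extent-of-variance %.2f\n",
              x$cb_blockade, x$cb_assault, x$cb_both, x$extent_of_variance))
  invisible(x)
}

#' Inter-explant heterogeneity for one patient
#'
#' Flags a patient as heterogeneous when any of the five pathway states or
#' the platinum class is discordant across that patient's explants.
#' Single-explant patients are never flagged.
#'
#' @param signatures List of `explant_signature` objects
#'   (see [assemble_explant()]) belonging to one patient.
#' @return List with `flag` (logical) and `discordant` (character vector
#'   of discordant pathway/class names).
#' @export
inter_explant_heterogeneity <- function(signatures) {
  if (!length(signatures)) {
    stop_ddr("at least one explant signature is required", class = "ddr_schema_error")
  }
  if (length(signatures) == 1) return(list(flag = FALSE, discordant = character(0)))
  fields <- c("HR", "NHEJ", "BER", "NER", "MMR", "platinum")
  discordant <- character(0)
  for (f in fields) {
    states <- vapply(signatures, function(s) {
      if (f == "platinum") s$platinum_class else s$calls[[f]]$state %||% NA_character_
    }, character(1))
    states <- states[!is.na(states)]
    if (length(unique(states)) > 1) discordant <- c(discordant, f)
  }
  list(flag = length(discordant) > 0, discordant = discordant)
}
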