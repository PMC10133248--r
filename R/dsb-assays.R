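#' Score homologous recombination capacity from Rad51/gamma-H2AX foci
#'
#' HR competence is read from irradiation-induced Rad51 focus formation.
#' QC first requires evidence of sufficient cellular assault: at least a
#' twofold increase in mean gamma-H2AX foci in irradiated vs control
#' nuclei. Given QC, the HR score is the fold change in mean Rad51 foci
#' (irradiated / control) and the explant is called competent when the
#' fold change reaches `fold_threshold` (inclusive).
#'
#' @param foci Data frame with columns `explant_id`, `nucleus_id`,
#'   `condition` (`"control"`/`"irradiated"`), `gH2AX_foci`, `rad51_foci`.
#'   One explant per call.
#' @param fold_threshold Rad51 fold-change competence threshold
#'   (default 2, inclusive).
#' @param qc_fold gamma-H2AX fold-change required to demonstrate assault
#'   (default 2, inclusive).
#' @param min_nuclei Minimum scored nuclei per condition (default 50);
#'   shortfall yields a QC-failure call, not an error.
#' @return A [ddr_call()] for pathway `"HR"`. On QC failure the state is
#'   `NA` and the evidence records the reason.
#' @export
score_hr <- function(foci, fold_threshold = 2.0, qc_fold = 2.0, min_nuclei = 50) {
  assert_cols(foci, c("explant_id", "condition", "gH2AX_foci", "rad51_foci"), "foci")
  n_by <- table(factor(foci$condition, levels = c("control", "irradiated")))
  means <- function(col, cond) mean(foci[[col]][foci$condition == cond])

  if (any(n_by < min_nuclei)) {
    return(ddr_call("HR", score = NA_real_, state = NA, qc_pass = FALSE,
                    evidence = list(reason = "insufficient nuclei",
                                    n_control = unname(n_by[["control"]]),
                                    n_irradiated = unname(n_by[["irradiated"]]),
                                    min_nuclei = min_nuclei)))
  }
  gh_ratio <- means("gH2AX_foci", "irradiated") / means("gH2AX_foci", "control")
  rad_ctrl <- means("rad51_foci", "control")
  rad_irr <- means("rad51_foci", "irradiated")
  score <- rad_irr / rad_ctrl
  qc <- is.finite(gh_ratio) && gh_ratio >= qc_fold
  evidence <- list(gh2ax_fold = gh_ratio, rad51_control_mean = rad_ctrl,
                   rad51_irradiated_mean = rad_irr,
                   # per-cell fraction exceeding threshold, exposed as evidence
                   frac_cells_induced = mean(foci$rad51_foci[foci$condition == "irradiated"] >=
                                               fold_threshold * rad_ctrl))
  if (!qc) {
    return(ddr_call("HR", score = score, state = NA, qc_pass = FALSE, evidence = evidence))
  }
  ddr_call("HR", score = score,
           state = if (score >= fold_threshold) "competent" else "defective",
           qc_pass = TRUE, evidence = evidence)
}

NHEJ_CONFORMATIONS <- c("blunt", "overhang_5to3", "overhang_3to5")

#' Score one plasmid conformation of the host-cell reactivation assay
#'
#' The repair fraction for a break conformation is the best (maximum over
#' the 24/48/72 h timepoints) ratio of its GFP-positive event rate to the
#' uncut-control GFP-positive rate at the same timepoint, clamped to
#' \[0, 1\]. The fraction is discretised to an ordinal 0-3 at cut points
#' 0.05 / 0.20 / 0.50.
#'
#' @param events Reporter event table with columns `explant_id`,
#'   `conformation`, `timepoint_h`, `cell_id`, `gfp_positive`.
#' @param conformation One of `"blunt"`, `"overhang_5to3"`,
#'   `"overhang_3to5"`.
#' @param min_events Minimum events per conformation (default 1000).
#' @param cuts Ordinal cut points (defaults `c(0.05, 0.20, 0.50)`).
#' @return List with `repair_fraction`, `ordinal`, and per-timepoint rates.
#' @export
score_nhej_condition <- function(events, conformation, min_events = 1000,
                                 cuts = c(0.05, 0.20, 0.50)) {
  assert_cols(events, c("conformation", "timepoint_h", "gfp_positive"), "reporter")
  if (!conformation %in% events$conformation) {
    stop_ddr("conformation '", conformation, "' absent from event table",
             class = "ddr_partial_assay_error")
  }
  if (!"uncut_control" %in% events$conformation) {
    stop_ddr("uncut control conformation absent", class = "ddr_partial_assay_error")
  }
  n_conf <- sum(events$conformation == conformation)
  if (n_conf < min_events) {
    stop_ddr("only ", n_conf, " events for conformation '", conformation,
             "' (minimum ", min_events, ")", class = "ddr_partial_assay_error")
  }
  rate <- function(conf, tp) {
    sel <- events$conformation == conf & events$timepoint_h == tp
    if (!any(sel)) return(NA_real_)
    mean(events$gfp_positive[sel])
  }
  tps <- sort(unique(events$timepoint_h))
  ctrl <- vapply(tps, function(tp) rate("uncut_control", tp), numeric(1))
  if (all(is.na(ctrl)) || all(ctrl[!is.na(ctrl)] == 0)) {
    stop_ddr("zero GFP-positive rate in uncut control: transfection failure",
             class = "ddr_transfection_error")
  }
  conf_rate <- vapply(tps, function(tp) rate(conformation, tp), numeric(1))
  ratio <- ifelse(ctrl > 0, conf_rate / ctrl, NA_real_)
  frac <- clamp(max(ratio, na.rm = TRUE), 0, 1)
  ordinal <- findInterval(frac, cuts)    # 0:<0.05, 1:<0.20, 2:<0.50, 3 otherwise
  list(repair_fraction = frac, ordinal = as.integer(ordinal),
       timepoints = tps, conformation_rates = conf_rate, control_rates = ctrl)
}

#' Score NHEJ capacity from host-cell reactivation reporter events
#'
#' The three break-conformation ordinals (see [score_nhej_condition()]) are
#' summed into an explant capacity score on 0-9. The default competence
#' rule requires at least `min_competent_conformations` conformations with
#' ordinal >= 2, i.e. reproducible repair of more than one break geometry.
#'
#' @inheritParams score_nhej_condition
#' @param min_competent_conformations Competence rule: number of
#'   conformations that must reach ordinal >= 2 (default 2).
#' @return A [ddr_call()] for pathway `"NHEJ"`; evidence holds per-
#'   conformation fractions and ordinals. The sum-of-ordinals integration
#'   is an artifact default and is recorded in the evidence metadata.
#' @export
score_nhej <- function(events, min_events = 1000, cuts = c(0.05, 0.20, 0.50),
                       min_competent_conformations = 2) {
  missing_conf <- setdiff(NHEJ_CONFORMATIONS, unique(events$conformation))
  if (length(missing_conf)) {
    stop_ddr("missing break conformation(s): ", paste(missing_conf, collapse = ", "),
             class = "ddr_partial_assay_error")
  }
  per <- lapply(NHEJ_CONFORMATIONS, function(cf) {
    score_nhej_condition(events, cf, min_events = min_events, cuts = cuts)
  })
  names(per) <- NHEJ_CONFORMATIONS
  ordinals <- vapply(per, `[[`, integer(1), "ordinal")
  fractions <- vapply(per, `[[`, numeric(1), "repair_fraction")
  res <- nhej_integrate(ordinals, min_competent_conformations)
  ddr_call("NHEJ", score = res$score, state = res$state, qc_pass = TRUE,
           evidence = list(ordinals = ordinals, repair_fractions = fractions,
                           integration = "sum_of_ordinals",
                           rule = sprintf(">=%d conformations with ordinal >= 2",
                                          min_competent_conformations)))
}

#' Integrate three conformation ordinals into an NHEJ capacity call
#'
#' @param ordinals Integer vector of three ordinals in 0-3.
#' @param min_competent_conformations Number of conformations that must
#'   reach ordinal >= 2 for competence (default 2).
#' @return List with `score` (sum, 0-9) and `state`.
#' @export
nhej_integrate <- function(ordinals, min_competent_conformations = 2) {
  if (length(ordinals) != 3 || any(!ordinals %in% 0:3)) {
    stop_ddr("ordinals must be three values in 0..3", class = "ddr_schema_error")
  }
  list(score = sum(ordinals),
       state = if (sum(ordinals >= 2) >= min_competent_conformations)
         "competent" else "defective")
}
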