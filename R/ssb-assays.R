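COMET_CONDITIONS <- c("1_vehicle", "2_blockade", "3_assault", "4_assault_plus_blockade")

#' Summarise a four-condition comet table
#'
#' Computes robust per-condition summaries of the alkaline comet assay:
#' the median and IQR of tail %DNA and the scored-comet count for each of
#' the four incubation conditions (vehicle, pathway blockade, genomic
#' assault, assault during blockade).
#'
#' @param records Comet table with columns `explant_id`, `pathway`
#'   (`"BER"`/`"NER"`), `condition`, `comet_id`, `tail_pct_dna`. One
#'   explant and one pathway per call.
#' @param min_comets Minimum scored comets per condition (default 500).
#' @return Object of class `comet_summary`: medians `m1..m4`, IQRs,
#'   counts `n1..n4`, and the pathway label.
#' @export
comet_condition_summary <- function(records, min_comets = 500) {
  assert_cols(records, c("explant_id", "pathway", "condition", "tail_pct_dna"), "comet")
  if (any(records$tail_pct_dna < 0 | records$tail_pct_dna > 100)) {
    stop_ddr("tail_pct_dna outside [0, 100]", class = "ddr_schema_error")
  }
  missing_cond <- setdiff(COMET_CONDITIONS, unique(records$condition))
  if (length(missing_cond)) {
    stop_ddr("missing comet condition(s): ", paste(missing_cond, collapse = ", "),
             class = "ddr_partial_assay_error")
  }
  by_cond <- split(records$tail_pct_dna,
                   factor(records$condition, levels = COMET_CONDITIONS))
  n <- vapply(by_cond, length, integer(1))
  short <- names(n)[n < min_comets]
  if (length(short)) {
    stop_ddr("comet count below ", min_comets, " in condition(s): ",
             paste(short, collapse = ", "), class = "ddr_partial_assay_error")
  }
  structure(list(
    pathway = unique(records$pathway)[1],
    explant_id = unique(records$explant_id)[1],
    medians = vapply(by_cond, stats::median, numeric(1)),
    iqrs = vapply(by_cond, stats::IQR, numeric(1)),
    counts = n
  ), class = "comet_summary")
}

#' Score BER or NER capacity from a comet condition summary
#'
#' The repair fraction contrasts residual damage after recovery with and
#' without pathway blockade:
#' `R = clamp((m4 - m3) / (m4 - m1), 0, 1)`,
#' where `m1` is the vehicle median tail %DNA, `m3` the median after
#' genomic assault followed by recovery, and `m4` the median when the
#' pathway is blocked during that recovery (no repair possible). The assay
#' is valid only when the blocked condition demonstrates induced damage:
#' `m4 - m1 >= d_min` percentage points.
#'
#' @param summary A `comet_summary` from [comet_condition_summary()].
#' @param pathway `"BER"` or `"NER"`; defaults to the summary's pathway.
#' @param competence_threshold Repair fraction for a competent call
#'   (default 0.5, inclusive).
#' @param d_min Minimum induced damage `m4 - m1` in percentage points
#'   (default 5); below this the call is a QC failure.
#' @return A [ddr_call()] with score `R`; evidence records the medians,
#'   the blockade-only shift `m2 - m1`, and the IQRs.
#' @export
score_ssb_pathway <- function(summary, pathway = summary$pathway,
                              competence_threshold = 0.5, d_min = 5) {
  if (!inherits(summary, "comet_summary")) {
    stop_ddr("summary must come from comet_condition_summary()", class = "ddr_schema_error")
  }
  pathway <- match.arg(pathway, c("BER", "NER"))
  m <- unname(summary$medians)
  evidence <- list(medians = summary$medians, iqrs = summary$iqrs,
                   counts = summary$counts, blockade_shift = m[2] - m[1],
                   induced_damage = m[4] - m[1])
  if (!(m[4] - m[1] >= d_min)) {
    evidence$reason <- if (m[4] <= m[1]) "assault failure (m4 <= m1)" else
      sprintf("induced damage %.1f below d_min %.1f", m[4] - m[1], d_min)
    return(ddr_call(pathway, score = NA_real_, state = NA, qc_pass = FALSE,
                    evidence = evidence))
  }
  R <- clamp((m[4] - m[3]) / (m[4] - m[1]), 0, 1)
  ddr_call(pathway, score = R,
           state = if (R >= competence_threshold) "competent" else "defective",
           qc_pass = TRUE, evidence = evidence)
}

#' The default 22-gene extended mismatch-repair panel
#'
#' Gene membership is a configuration resource: the default list covers
#' the canonical MutS/MutL homologues plus the replication-coupled
#' excision/resynthesis machinery, and can be replaced by any character
#' vector or one-gene-per-line text file.
#'
#' @param file Optional path to a one-gene-per-line panel file.
#' @return Character vector of gene symbols.
#' @export
mmr_panel <- function(file = NULL) {
  if (!is.null(file)) {
    genes <- readLines(file)
    genes <- trimws(genes[nzchar(trimws(genes)) & !startsWith(trimws(genes), "#")])
    return(genes)
  }
  default <- system.file("extdata", "mmr22_panel.txt", package = "ddrprofiler")
  if (nzchar(default)) return(mmr_panel(default))
  c("MLH1", "MLH3", "MSH2", "MSH3", "MSH6", "PMS1", "PMS2", "EXO1",
    "POLD1", "POLD2", "POLD3", "POLD4", "POLE", "PCNA", "LIG1",
    "RFC1", "RFC2", "RFC3", "RFC4", "RFC5", "RPA1", "RPA2")
}

IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

#' Score MMR capacity from an impact-annotated variant table
#'
#' An explant is MMR-defective when at least one variant inside the
#' mismatch-repair gene panel is rated `HIGH` impact by both annotators
#' (SnpEff and VEP; `mode = "intersect"`) or by either (`mode = "union"`).
#' The score is the count of qualifying variants.
#'
#' @param variants Data frame with columns `explant_id`, `gene`,
#'   `impact_snpeff`, `impact_vep`, `consequence`.
#' @param mode `"intersect"` (default) or `"union"` annotator agreement.
#' @param panel Character vector of panel gene symbols
#'   (default [mmr_panel()]).
#' @return A [ddr_call()] for pathway `"MMR"`; evidence lists the
#'   qualifying variants and the in-panel variant count by impact.
#' @export
score_mmr <- function(variants, mode = c("intersect", "union"), panel = mmr_panel()) {
  mode <- match.arg(mode)
  assert_cols(variants, c("gene", "impact_snpeff", "impact_vep"), "variant")
  bad <- !(variants$impact_snpeff %in% IMPACT_LEVELS) |
    !(variants$impact_vep %in% IMPACT_LEVELS)
  if (any(bad)) {
    i <- which(bad)[1]
    stop_ddr("unknown impact label in record ", i, " (gene ", variants$gene[i],
             "): snpeff='", variants$impact_snpeff[i], "', vep='",
             variants$impact_vep[i], "'", class = "ddr_schema_error")
  }
  in_panel <- variants$gene %in% panel
  high <- if (mode == "intersect") {
    variants$impact_snpeff == "HIGH" & variants$impact_vep == "HIGH"
  } else {
    variants$impact_snpeff == "HIGH" | variants$impact_vep == "HIGH"
  }
  qualifying <- variants[in_panel & high, , drop = FALSE]
  n_qual <- nrow(qualifying)
  ddr_call("MMR", score = n_qual,
           state = if (n_qual >= 1) "defective" else "competent",
           qc_pass = TRUE,
           evidence = list(mode = mode, qualifying = qualifying,
                           n_in_panel = sum(in_panel),
                           panel_size = length(panel)))
}
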