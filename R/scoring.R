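#' Score one explant from its raw assay tables
#'
#' Runs all scorers — HR foci, NHEJ host-cell reactivation, BER/NER
#' comet, MMR variant panel, GR50 cytotoxicity, DCFDA ROS, JC-10
#' mitochondrial — and assembles the explant signature, including the
#' class-balance survivorship metrics from the BER comet table.
#'
#' @param foci,reporter,comet,viability,dcfda,jc10,variants Per-explant
#'   assay tables (see the reader functions for schemas). Any table may
#'   be `NULL`; the corresponding calls/states are then missing.
#' @param explant_id,patient_id Identifiers.
#' @param seeded_cells Comet assay input cells per condition
#'   (default 400000), the class-balance denominator.
#' @param opts Named list of scorer options: `min_nuclei`, `min_events`,
#'   `min_comets`, `fold_threshold`, `competence_threshold`, `d_min`,
#'   `mmr_mode`, `ros_threshold`, `mito_threshold`,
#'   `platinum_threshold_uM`.
#' @return An `explant_signature`.
#' @export
score_explant <- function(foci, reporter, comet, viability, dcfda, jc10,
                          variants, explant_id = NULL, patient_id = NULL,
                          seeded_cells = 400000, opts = list()) {
  o <- utils::modifyList(list(
    min_nuclei = 50, min_events = 1000, min_comets = 500,
    fold_threshold = 2.0, competence_threshold = 0.5, d_min = 5,
    mmr_mode = "intersect", ros_threshold = 2.0, mito_threshold = 0.2,
    platinum_threshold_uM = 48
  ), opts)

  hr <- score_hr(foci, fold_threshold = o$fold_threshold, min_nuclei = o$min_nuclei)
  nhej <- score_nhej(reporter, min_events = o$min_events)
  ssb_calls <- lapply(c("BER", "NER"), function(p) {
    recs <- comet[comet$pathway == p, , drop = FALSE]
    cs <- comet_condition_summary(recs, min_comets = o$min_comets)
    score_ssb_pathway(cs, p, competence_threshold = o$competence_threshold,
                      d_min = o$d_min)
  })
  mmr <- score_mmr(variants, mode = o$mmr_mode)
  gr <- fit_gr_curve(viability)
  ros <- score_ros(dcfda, ros_threshold = o$ros_threshold)
  mito <- score_mito(jc10, mito_threshold = o$mito_threshold)

  ber_recs <- comet[comet$pathway == "BER", , drop = FALSE]
  counts <- vapply(COMET_CONDITIONS,
                   function(cc) sum(ber_recs$condition == cc), numeric(1))
  cb <- class_balance(seeded_cells, counts,
                      ber_recs$tail_pct_dna[ber_recs$condition == "3_assault"])

  assemble_explant(c(list(hr, nhej), ssb_calls, list(mmr)),
                   gr50 = gr, ros = ros, mito = mito, cb = cb,
                   explant_id = explant_id, patient_id = patient_id,
                   platinum_threshold_uM = o$platinum_threshold_uM)
}

#' Score every explant of a cohort and aggregate to patients
#'
#' @param cohort A `ddr_cohort` from [generate_cohort()], or a named list
#'   of combined assay tables (each with an `explant_id` column) plus a
#'   `clinical` table.
#' @param strategy Patient merge strategy (see [aggregate_patient()]).
#' @param opts Scorer options forwarded to [score_explant()].
#' @return List with `explants` (signature list), `patients` (signature
#'   list), `explant_df` and `patient_df` (flat tables).
#' @export
score_cohort <- function(cohort, strategy = "defective_dominant", opts = list()) {
  assays <- if (inherits(cohort, "ddr_cohort")) cohort$assays else cohort
  seeded <- if (inherits(cohort, "ddr_cohort")) cohort$config$sizes$seeded_cells else 400000
  ids <- unique(assays$foci$explant_id)
  by_id <- lapply(assays, function(tb) split(tb, tb$explant_id))
  pat_of <- function(id) sub("-E\\d+$", "", id)

  explants <- lapply(ids, function(id) {
    score_explant(
      foci = by_id$foci[[id]], reporter = by_id$reporter[[id]],
      comet = by_id$comet[[id]], viability = by_id$viability[[id]],
      dcfda = by_id$dcfda[[id]], jc10 = by_id$jc10[[id]],
      variants = by_id$variants[[id]],
      explant_id = id, patient_id = pat_of(id),
      seeded_cells = seeded, opts = opts
    )
  })
  names(explants) <- ids

  pids <- vapply(explants, function(e) e$patient_id, character(1))
  routes <- if (inherits(cohort, "ddr_cohort")) {
    stats::setNames(cohort$clinical$route, cohort$clinical$patient_id)
  } else NULL
  patients <- lapply(split(explants, pids), function(exs) {
    pid <- exs[[1]]$patient_id
    aggregate_patient(exs, strategy = strategy,
                      route = if (!is.null(routes)) routes[[pid]] else NA_character_)
  })

  list(explants = explants, patients = patients,
       explant_df = signatures_to_df(explants),
       patient_df = signatures_to_df(unname(patients)))
}

#' Numeric feature encoding of patient signatures for classification
#'
#' Binary pathway states (competent = 1), platinum class (resistant = 1),
#' metabolic states (ROS homoeostatic = 1, mitochondria dysfunctional =
#' 1), and the class-balance numerics (survivorship fold change under
#' assault-plus-blockade and intra-explant extent-of-variance).
#'
#' @param patients List of `patient_signature`s or a data frame from
#'   [signatures_to_df()].
#' @param include_class_balance Include the two numeric class-balance
#'   features (default `TRUE`).
#' @return Numeric data frame, one row per patient, rownames = ids.
#' @export
signature_features <- function(patients, include_class_balance = TRUE) {
  df <- if (is.data.frame(patients)) patients else signatures_to_df(unname(patients))
  out <- data.frame(
    hr = as.numeric(df$hr == "competent"),
    nhej = as.numeric(df$nhej == "competent"),
    ber = as.numeric(df$ber == "competent"),
    ner = as.numeric(df$ner == "competent"),
    mmr = as.numeric(df$mmr == "competent"),
    platinum_resistant = as.numeric(df$platinum == "resistant"),
    ros_homoeostatic = as.numeric(df$ros == "homoeostatic"),
    mito_dysfunctional = as.numeric(df$mito == "dysfunctional"),
    row.names = df$id
  )
  if (include_class_balance && "cb_both" %in% names(df)) {
    out$cb_both <- df$cb_both
    out$extent_of_variance <- df$extent_of_variance
  }
  out
}
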