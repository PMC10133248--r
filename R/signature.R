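DDR_PATHWAYS <- c("HR", "NHEJ", "BER", "NER", "MMR")

#' Assemble an explant signature from its assay calls
#'
#' Couples the five pathway calls with the GR50 fit, metabolic states and
#' class-balance metrics, and computes the aggregate competence sums:
#' `dsb_competence` (competent count over HR + NHEJ, 0-2),
#' `ssb_competence` (over BER + NER + MMR, 0-3) and their total (0-5).
#' A QC-failed call contributes a missing state: the sums then cover the
#' remaining pathways and `missing_flag` is set rather than imputing.
#'
#' @param calls List of five [ddr_call()] objects (one per pathway, any
#'   order; duplicates are an error).
#' @param gr50 A `gr_fit` from [fit_gr_curve()] (or `NULL`).
#' @param ros Result of [score_ros()] (or `NULL`).
#' @param mito Result of [score_mito()] (or `NULL`).
#' @param cb A [class_balance()] (or `NULL`).
#' @param explant_id,patient_id Identifiers; default from the GR fit.
#' @param platinum_threshold_uM Passed to [classify_platinum()].
#' @return Object of class `explant_signature`.
#' @export
assemble_explant <- function(calls, gr50 = NULL, ros = NULL, mito = NULL,
                             cb = NULL, explant_id = NULL, patient_id = NULL,
                             platinum_threshold_uM = 48) {
  pw <- vapply(calls, function(x) x$pathway, character(1))
  if (anyDuplicated(pw)) {
    stop_ddr("duplicate pathway call: ", pw[duplicated(pw)][1], class = "ddr_schema_error")
  }
  missing_pw <- setdiff(DDR_PATHWAYS, pw)
  if (length(missing_pw)) {
    stop_ddr("missing pathway call(s): ", paste(missing_pw, collapse = ", "),
             class = "ddr_schema_error")
  }
  names(calls) <- pw
  calls <- calls[DDR_PATHWAYS]
  states <- vapply(calls, function(x) x$state %||% NA_character_, character(1))
  comp <- states == "competent"
  dsb <- sum(comp[c("HR", "NHEJ")], na.rm = TRUE)
  ssb <- sum(comp[c("BER", "NER", "MMR")], na.rm = TRUE)
  structure(list(
    explant_id = explant_id %||% (if (!is.null(gr50)) gr50$explant_id else NA_character_),
    patient_id = patient_id,
    calls = calls,
    states = states,
    gr50_uM = if (!is.null(gr50)) gr50$gr50_uM else NA_real_,
    platinum_class = if (!is.null(gr50)) classify_platinum(gr50, platinum_threshold_uM) else NA_character_,
    ros_class = if (!is.null(ros)) ros$state else NA_character_,
    ros_score = if (!is.null(ros)) ros$score else NA_real_,
    mito_class = if (!is.null(mito)) mito$state else NA_character_,
    mito_response = if (!is.null(mito)) mito$response else NA_real_,
    class_balance = cb,
    dsb_competence = dsb,
    ssb_competence = ssb,
    total_competence = dsb + ssb,
    missing_flag = any(is.na(states))
  ), class = "explant_signature")
}

#' @export
print.explant_signature <- function(x, ...) {
  cat(sprintf("<explant_signature> %s (patient %s)\n", x$explant_id, x$patient_id %||% "?"))
  cat("  states:", paste(sprintf("%s=%s", names(x$states), x$states), collapse = " "), "\n")
  cat(sprintf("  platinum %s (GR50 %.3g uM), ROS %s, mito %s; competence %d/5%s\n",
              x$platinum_class, x$gr50_uM, x$ros_class, x$mito_class,
              x$total_competence, if (x$missing_flag) " [missing states]" else ""))
  invisible(x)
}

# numeric score merge thresholds used by the weighted_mean strategy;
# artifact defaults recorded in output provenance
MERGE_THRESHOLDS <- c(HR = 2.0, NHEJ = 4.5, BER = 0.5, NER = 0.5, MMR = 1.0)

#' Aggregate explant signatures into a patient signature
#'
#' Merges one patient's explant signatures into a patient-resolution
#' summary. Four named strategies accommodate discordant values:
#' \describe{
#'   \item{defective_dominant}{(default) a pathway is defective if any
#'     explant calls it defective — the conservative triage reading.}
#'   \item{majority}{most frequent state wins; ties resolve defective.}
#'   \item{worst_case}{defective-dominant states plus worst-case numeric
#'     scores (minimum capacity, maximum MMR hit count).}
#'   \item{weighted_mean}{numeric scores combined by weighted mean
#'     (weights default equal, configurable per explant) then thresholded
#'     (HR fold 2, NHEJ 4.5, BER/NER 0.5; MMR defective when the merged
#'     hit count reaches 1).}
#' }
#' Platinum is always merged resistant-dominant (maximum GR50), ROS and
#' mitochondrial states dysfunctional-dominant, numeric class-balance
#' metrics by weighted mean, and the inter-explant heterogeneity flag from
#' [inter_explant_heterogeneity()]. Missing states propagate as missing.
#'
#' @param explants List of `explant_signature` objects, all for the same
#'   patient.
#' @param strategy Merge strategy (see above).
#' @param weights Optional numeric per-explant weights (recycled
#'   normalised); default equal.
#' @param route Optional treatment route label (`"PS"`/`"IDS"`).
#' @return Object of class `patient_signature`.
#' @export
aggregate_patient <- function(explants,
                              strategy = c("defective_dominant", "majority",
                                           "worst_case", "weighted_mean"),
                              weights = NULL, route = NA_character_) {
  strategy <- match.arg(strategy)
  if (!length(explants)) {
    stop_ddr("empty explant list", class = "ddr_integrity_error")
  }
  pids <- unique(vapply(explants, function(e) e$patient_id %||% NA_character_, character(1)))
  pids <- pids[!is.na(pids)]
  if (length(pids) > 1) {
    stop_ddr("mixed patient ids in aggregate_patient: ", paste(pids, collapse = ", "),
             class = "ddr_integrity_error")
  }
  w <- weights %||% rep(1, length(explants))
  w <- rep_len(w, length(explants)); w <- w / sum(w)

  merge_state <- function(states, scores) {
    ok <- !is.na(states)
    if (!any(ok)) return(NA_character_)
    st <- states[ok]
    switch(strategy,
      defective_dominant = if (any(st == "defective")) "defective" else "competent",
      worst_case = if (any(st == "defective")) "defective" else "competent",
      majority = {
        tab <- table(st)
        if (length(tab) > 1 && tab[["competent"]] == tab[["defective"]]) "defective"
        else names(which.max(tab))
      },
      weighted_mean = NA_character_  # resolved from merged score below
    )
  }

  states <- character(0); scores <- numeric(0)
  for (p in DDR_PATHWAYS) {
    st <- vapply(explants, function(e) e$states[[p]], character(1))
    sc <- vapply(explants, function(e) e$calls[[p]]$score %||% NA_real_, numeric(1))
    ok <- !is.na(st) & !is.na(sc)
    merged_score <- if (!any(ok)) NA_real_ else switch(strategy,
      worst_case = if (p == "MMR") max(sc[ok]) else min(sc[ok]),
      sum(w[ok] * sc[ok]) / sum(w[ok])
    )
    merged_state <- if (strategy == "weighted_mean") {
      if (is.na(merged_score)) NA_character_
      else if (p == "MMR") {
        if (merged_score >= MERGE_THRESHOLDS[[p]]) "defective" else "competent"
      } else {
        if (merged_score >= MERGE_THRESHOLDS[[p]]) "competent" else "defective"
      }
    } else merge_state(st, sc)
    states[p] <- merged_state
    scores[p] <- merged_score
  }

  gr50s <- vapply(explants, function(e) e$gr50_uM, numeric(1))
  plat <- vapply(explants, function(e) e$platinum_class %||% NA_character_, character(1))
  plat_class <- if (all(is.na(plat))) NA_character_ else
    if (any(plat == "resistant", na.rm = TRUE)) "resistant" else "sensitive"
  ros <- vapply(explants, function(e) e$ros_class %||% NA_character_, character(1))
  mito <- vapply(explants, function(e) e$mito_class %||% NA_character_, character(1))
  dom <- function(v, bad) if (all(is.na(v))) NA_character_ else
    if (any(v == bad, na.rm = TRUE)) bad else v[!is.na(v)][1]

  wmean <- function(get) {
    vals <- vapply(explants, get, numeric(1))
    ok <- !is.na(vals)
    if (!any(ok)) NA_real_ else sum(w[ok] * vals[ok]) / sum(w[ok])
  }
  het <- inter_explant_heterogeneity(explants)
  comp <- states == "competent"
  dsb <- sum(comp[c("HR", "NHEJ")], na.rm = TRUE)
  ssb <- sum(comp[c("BER", "NER", "MMR")], na.rm = TRUE)

  structure(list(
    patient_id = if (length(pids)) pids else NA_character_,
    n_explants = length(explants),
    strategy = strategy,
    states = states,
    scores = scores,
    gr50_uM = if (all(is.na(gr50s))) NA_real_ else max(gr50s, na.rm = TRUE),
    platinum_class = plat_class,
    ros_class = dom(ros, "dysfunctional"),
    mito_class = dom(mito, "dysfunctional"),
    cb_blockade = wmean(function(e) if (is.null(e$class_balance)) NA_real_ else e$class_balance$cb_blockade),
    cb_assault = wmean(function(e) if (is.null(e$class_balance)) NA_real_ else e$class_balance$cb_assault),
    cb_both = wmean(function(e) if (is.null(e$class_balance)) NA_real_ else e$class_balance$cb_both),
    extent_of_variance = wmean(function(e) if (is.null(e$class_balance)) NA_real_ else e$class_balance$extent_of_variance),
    heterogeneity_flag = het$flag,
    discordant = het$discordant,
    dsb_competence = dsb,
    ssb_competence = ssb,
    total_competence = dsb + ssb,
    missing_flag = any(is.na(states)),
    route = route
  ), class = "patient_signature")
}

#' @export
print.patient_signature <- function(x, ...) {
  cat(sprintf("<patient_signature> %s (%d explant%s, strategy %s)\n",
              x$patient_id, x$n_explants, if (x$n_explants > 1) "s" else "", x$strategy))
  cat("  states:", paste(sprintf("%s=%s", names(x$states), x$states), collapse = " "), "\n")
  cat(sprintf("  platinum %s (GR50 %.3g), ROS %s, mito %s; heterogeneity %s\n",
              x$platinum_class, x$gr50_uM, x$ros_class, x$mito_class,
              if (x$heterogeneity_flag) paste0("YES [", paste(x$discordant, collapse = ","), "]") else "no"))
  invisible(x)
}

#' Flatten signatures to a data frame
#'
#' One row per explant or patient signature; list-backed evidence is
#' dropped, states and numeric metrics are kept.
#'
#' @param signatures List of `explant_signature` or `patient_signature`
#'   objects.
#' @return A data frame.
#' @export
signatures_to_df <- function(signatures) {
  rows <- lapply(signatures, function(s) {
    base <- data.frame(
      id = s$explant_id %||% s$patient_id,
      patient_id = s$patient_id %||% NA_character_,
      hr = s$states[["HR"]], nhej = s$states[["NHEJ"]], ber = s$states[["BER"]],
      ner = s$states[["NER"]], mmr = s$states[["MMR"]],
      gr50_uM = s$gr50_uM, platinum = s$platinum_class,
      ros = s$ros_class, mito = s$mito_class,
      dsb_competence = s$dsb_competence, ssb_competence = s$ssb_competence,
      total_competence = s$total_competence,
      missing_flag = s$missing_flag,
      stringsAsFactors = FALSE
    )
    if (inherits(s, "patient_signature")) {
      base$heterogeneity_flag <- s$heterogeneity_flag
      base$cb_both <- s$cb_both
      base$extent_of_variance <- s$extent_of_variance
      base$route <- s$route
    } else if (!is.null(s$class_balance)) {
      base$cb_both <- s$class_balance$cb_both
      base$extent_of_variance <- s$class_balance$extent_of_variance
    } else {
      base$cb_both <- NA_real_
      base$extent_of_variance <- NA_real_
    }
    base
  })
  do.call(rbind, rows)
}

#' Serialise a signature to JSON and back
#'
#' @param signature An `explant_signature` or `patient_signature`.
#' @param path File path; when `NULL` the JSON string is returned.
#' @return `signature_to_json()`: path or JSON string;
#'   `signature_from_json()`: the signature object.
#' @export
signature_to_json <- function(signature, path = NULL) {
  cls <- class(signature)[1]
  # named atomic vectors must become objects, not arrays, to keep names
  listify <- function(x) {
    if (is.list(x)) lapply(x, listify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  payload <- unclass(signature)
  # ddr_call and class_balance sub-objects flatten to plain lists
  if (!is.null(payload$calls)) payload$calls <- lapply(payload$calls, unclass)
  if (!is.null(payload$class_balance)) payload$class_balance <- unclass(payload$class_balance)
  payload <- listify(payload)
  payload$.class <- cls
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname signature_to_json
#' @param json JSON string or file path produced by [signature_to_json()].
#' @export
signature_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  cls <- x$.class; x$.class <- NULL
  if (!is.null(x$calls)) {
    x$calls <- lapply(x$calls, function(cl) {
      cl$evidence <- as.list(cl$evidence)
      structure(cl, class = "ddr_call")
    })
  }
  if (!is.null(x$class_balance) && length(x$class_balance)) {
    x$class_balance <- structure(x$class_balance, class = "class_balance")
  }
  x$states <- unlist(x$states)
  if (!is.null(x$scores)) x$scores <- unlist(x$scores)
  structure(x, class = cls)
}
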