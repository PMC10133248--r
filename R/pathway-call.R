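#' Construct a DDR pathway capacity call
#'
#' A pathway call couples a numeric capacity score (on a pathway-specific
#' scale) with a binary competent/defective state and the QC evidence that
#' backs it. When QC fails the state is undefined (`NA`) but the evidence is
#' retained so the failure mode can be inspected.
#'
#' @param pathway One of `"HR"`, `"NHEJ"`, `"BER"`, `"NER"`, `"MMR"`.
#' @param score Numeric capacity score; scale depends on the pathway
#'   (fold change for HR, summed ordinals 0-9 for NHEJ, repair fraction
#'   0-1 for BER/NER, qualifying variant count for MMR).
#' @param state `"competent"`, `"defective"`, or `NA` when `qc_pass` is
#'   `FALSE`.
#' @param qc_pass Logical; did the assay pass its QC gate?
#' @param evidence Named list of intermediate statistics.
#' @return An object of class `ddr_call`.
#' @export
ddr_call <- function(pathway, score, state, qc_pass, evidence = list()) {
  pathway <- match.arg(pathway, c("HR", "NHEJ", "BER", "NER", "MMR"))
  if (isTRUE(qc_pass) && !is.na(state)) {
    state <- match.arg(state, c("competent", "defective"))
    if (!is.finite(score)) {
      stop_ddr("pathway score must be finite when QC passes", class = "ddr_schema_error")
    }
  } else {
    state <- NA_character_
  }
  structure(
    list(pathway = pathway, score = score, state = state,
         qc_pass = isTRUE(qc_pass), evidence = evidence),
    class = "ddr_call"
  )
}

#' @export
print.ddr_call <- function(x, ...) {
  st <- if (is.na(x$state)) "state undefined (QC fail)" else x$state
  cat(sprintf("<ddr_call> %s: %s (score %.3g, QC %s)\n",
              x$pathway, st, x$score, if (x$qc_pass) "pass" else "FAIL"))
  invisible(x)
}
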