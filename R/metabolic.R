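#' Score ROS recovery state from a DCFDA dose-response table
#'
#' Retention at dose `d` is `rho(d) = mean F(d) / mean F(0)` — the DCFDA
#' fluorescence retained after the recovery period relative to unassaulted
#' wells. The retention score is the median of `rho` over the high-dose
#' arm (TBHP doses >= `high_dose_uM`), and the explant is homoeostatic
#' when the score does not exceed `ros_threshold`.
#'
#' @param data Data frame with columns `explant_id`, `dose_uM`,
#'   `replicate`, `fluorescence_au` (one explant per call).
#' @param ros_threshold Retention score above which the explant is called
#'   dysfunctional (default 2).
#' @param high_dose_uM Doses at or above this define the scored arm
#'   (default 32).
#' @return List with `state` (`"homoeostatic"`/`"dysfunctional"`),
#'   `score` (median high-dose retention) and the per-dose retention
#'   profile.
#' @export
score_ros <- function(data, ros_threshold = 2.0, high_dose_uM = 32) {
  assert_cols(data, c("dose_uM", "fluorescence_au"), "DCFDA")
  if (!any(data$dose_uM == 0)) {
    stop_ddr("zero-dose wells are required for normalisation",
             class = "ddr_normalisation_error")
  }
  if (any(data$fluorescence_au <= 0)) {
    stop_ddr("fluorescence readings must be positive", class = "ddr_schema_error")
  }
  mean_by_dose <- tapply(data$fluorescence_au, data$dose_uM, mean)
  doses <- as.numeric(names(mean_by_dose))
  rho <- mean_by_dose / mean_by_dose[[which(doses == 0)[1]]]
  high <- doses >= high_dose_uM
  if (!any(high)) {
    stop_ddr("no doses at or above ", high_dose_uM, " uM", class = "ddr_schema_error")
  }
  score <- stats::median(rho[high])
  list(state = if (score <= ros_threshold) "homoeostatic" else "dysfunctional",
       score = unname(score),
       retention = data.frame(dose_uM = doses, rho = as.numeric(rho)))
}

#' Score mitochondrial membrane state from a JC-10 dose-response table
#'
#' The JC-10 aggregate/monomer ratio `r(d) = mean(590 nm) / mean(525 nm)`
#' is normalised to 100% at zero dose. A functional (homoeostatic)
#' membrane depolarises under peroxide assault: the ratio falls
#' monotonically with dose and the top-dose response
#' `Delta = 1 - r(d_max) / r(0)` reaches `mito_threshold`. Explants whose
#' ratio shows no material response, or a non-monotone profile (Kendall
#' trend of `r` against dose > 0), are called dysfunctional.
#'
#' @param data Data frame with columns `explant_id`, `dose_mM`,
#'   `replicate`, `channel` (`"em525"`/`"em590"`), `fluorescence_au`.
#' @param mito_threshold Minimum top-dose response `Delta` for a
#'   homoeostatic call (default 0.2).
#' @return List with `state`, `response` (`Delta`), the Kendall trend
#'   statistic, and the normalised ratio profile (percent).
#' @export
score_mito <- function(data, mito_threshold = 0.2) {
  assert_cols(data, c("dose_mM", "channel", "fluorescence_au"), "JC-10")
  doses <- sort(unique(data$dose_mM))
  r <- vapply(doses, function(d) {
    sel525 <- data$dose_mM == d & data$channel == "em525"
    sel590 <- data$dose_mM == d & data$channel == "em590"
    if (!any(sel525) || !any(sel590)) {
      stop_ddr("both channels required at every dose (missing at ", d, " mM)",
               class = "ddr_schema_error")
    }
    mean(data$fluorescence_au[sel590]) / mean(data$fluorescence_au[sel525])
  }, numeric(1))
  r_pct <- 100 * r / r[1]
  delta <- 1 - r[length(r)] / r[1]
  trend <- if (stats::sd(r) == 0) 0 else stats::cor(doses, r, method = "kendall")
  state <- if (delta >= mito_threshold && trend <= 0) "homoeostatic" else "dysfunctional"
  list(state = state, response = delta, trend = trend,
       profile = data.frame(dose_mM = doses, ratio_pct = r_pct))
}
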