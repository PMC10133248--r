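#' Growth-rate-inhibition value for one treated well
#'
#' The GR metric normalises treated cell counts by the culture's own
#' untreated growth so that resistance calls are decoupled from basal
#' proliferation rate:
#' `GR = 2 ^ (log2(x_c / x0) / log2(x_ctrl / x0)) - 1`.
#' GR is 1 for untreated-equivalent growth, 0 at cytostasis and negative
#' for cytotoxic response (lower bound -1).
#'
#' @param x_c Treated endpoint cell count (proxy).
#' @param x0 Initial cell count (proxy).
#' @param x_ctrl Untreated endpoint count (proxy).
#' @return GR value(s) in (-1, Inf). Vectorised.
#' @export
gr_value <- function(x_c, x0, x_ctrl) {
  if (any(c(x_c, x0, x_ctrl) <= 0)) {
    stop_ddr("cell counts must be positive", class = "ddr_domain_error")
  }
  if (any(x_ctrl == x0)) {
    stop_ddr("x_ctrl must differ from x0 (culture must be proliferating)",
             class = "ddr_domain_error")
  }
  2^(log2(x_c / x0) / log2(x_ctrl / x0)) - 1
}

# Three-parameter GR dose-response sigmoid; equals 1 at c = 0.
gr_sigmoid <- function(conc, gr_inf, gec50, h) {
  gr_inf + (1 - gr_inf) / (1 + (conc / gec50)^h)
}

gr50_from_params <- function(gr_inf, gec50, h) {
  if (gr_inf >= 0.5) return(Inf)
  gec50 * (0.5 / (0.5 - gr_inf))^(1 / h)
}

#' Fit a GR dose-response curve and extract GR50
#'
#' Converts per-well counts to GR values ([gr_value()]), pools replicates
#' at each concentration with inverse-variance weights, and fits
#' `GR(c) = GR_inf + (1 - GR_inf) / (1 + (c / GEC50)^h)` by bounded least
#' squares (Levenberg-Marquardt seeded from a deterministic multi-start
#' grid). GR50 — the concentration where the fitted curve crosses 0.5 —
#' follows in closed form from the parameters; if the fitted curve never
#' reaches 0.5 on the tested range the GR50 is censored above the top
#' concentration and reported as `Inf`.
#'
#' @param plate Data frame with columns `dose_uM`, `replicate`, `count`,
#'   and either an `x0` column or the `x0` argument. The zero-dose wells
#'   anchor `x_ctrl` and are excluded from the log-dose fit.
#' @param x0 Initial cell count proxy (scalar); overrides the column.
#' @param cv_bound Replicate coefficient-of-variation bound; doses whose
#'   replicate GR CV exceeds it are flagged in the diagnostics.
#' @param bounds List of parameter bounds
#'   (`gr_inf` in \[-1, 1\], `h` in (0, 5\], `gec50` in (0, 10 * c_max\]).
#' @return Object of class `gr_fit` with components `explant_id`,
#'   `params` (GR_inf, GEC50, h), `gr50_uM` (`Inf` when censored),
#'   `censored`, `gr_table` (pooled GR per dose), `diagnostics`.
#' @seealso [classify_platinum()], [predict.gr_fit()]
#' @export
fit_gr_curve <- function(plate, x0 = NULL, cv_bound = 0.25,
                         bounds = list(gr_inf = c(-1, 1), h = c(1e-2, 5),
                                       gec50 = NULL)) {
  assert_cols(plate, c("dose_uM", "replicate", "count"), "viability plate")
  if (is.null(x0)) {
    if (!"x0" %in% names(plate)) {
      stop_ddr("x0 must be supplied as a column or argument", class = "ddr_schema_error")
    }
    x0 <- unique(plate$x0)[1]
  }
  doses <- sort(unique(plate$dose_uM))
  if (length(doses) < 2 || doses[1] != 0) {
    stop_ddr("concentration grid must start at 0 and be increasing",
             class = "ddr_schema_error")
  }
  x_ctrl <- mean(plate$count[plate$dose_uM == 0])
  treated <- plate[plate$dose_uM > 0, , drop = FALSE]
  gr_well <- gr_value(treated$count, x0, x_ctrl)

  by_dose <- split(gr_well, treated$dose_uM)
  dvec <- as.numeric(names(by_dose))
  gr_mean <- vapply(by_dose, mean, numeric(1))
  gr_var <- vapply(by_dose, function(g) stats::var(g), numeric(1))
  gr_cv <- sqrt(gr_var) / pmax(abs(gr_mean), 0.05)
  w <- 1 / pmax(gr_var, 1e-4)
  keep <- is.finite(gr_mean)
  if (sum(keep) < 6) {
    stop_ddr("fewer than 6 finite GR points; cannot fit", class = "ddr_fit_error")
  }
  dvec <- dvec[keep]; gr_mean <- gr_mean[keep]; w <- w[keep]
  c_max <- max(plate$dose_uM)
  gec50_bounds <- bounds$gec50 %||% c(c_max * 1e-4, 10 * c_max)

  sse <- function(p) sum(w * (gr_mean - gr_sigmoid(dvec, p[1], exp(p[2]), p[3]))^2)
  starts <- expand.grid(gr_inf = c(-0.5, 0, 0.4),
                        log_gec50 = log(exp(seq(log(gec50_bounds[1] * 10),
                                                log(c_max), length.out = 5))),
                        h = c(0.5, 1, 2, 4))
  best <- NULL
  lower <- c(bounds$gr_inf[1], log(gec50_bounds[1]), bounds$h[1])
  upper <- c(bounds$gr_inf[2], log(gec50_bounds[2]), bounds$h[2])
  for (i in seq_len(nrow(starts))) {
    p0 <- as.numeric(starts[i, ])
    fit <- tryCatch(
      stats::optim(p0, sse, method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    stop_ddr("GR curve fit failed to converge from every start",
             class = "ddr_fit_error")
  }
  # polish with Levenberg-Marquardt from the best multistart optimum
  df_fit <- data.frame(conc = dvec, gr = gr_mean, w = w)
  nls_fit <- tryCatch(
    minpack.lm::nlsLM(gr ~ gr_inf + (1 - gr_inf) / (1 + (conc / exp(lg))^h),
                      data = df_fit, weights = w,
                      start = list(gr_inf = best$par[1], lg = best$par[2],
                                   h = best$par[3]),
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  par <- if (!is.null(nls_fit)) {
    cf <- stats::coef(nls_fit); c(cf[["gr_inf"]], cf[["lg"]], cf[["h"]])
  } else best$par
  if (sse(par) > best$value) par <- best$par

  gr_inf <- par[1]; gec50 <- exp(par[2]); h <- par[3]
  gr50 <- gr50_from_params(gr_inf, gec50, h)
  censored <- !is.finite(gr50) || gr50 > c_max
  resid <- gr_mean - gr_sigmoid(dvec, gr_inf, gec50, h)

  structure(list(
    explant_id = if ("explant_id" %in% names(plate)) unique(plate$explant_id)[1] else NA_character_,
    params = c(GR_inf = gr_inf, GEC50 = gec50, h = h),
    gr50_uM = if (censored) Inf else gr50,
    censored = censored,
    censor_limit_uM = c_max,
    x0 = x0, x_ctrl = x_ctrl,
    gr_table = data.frame(dose_uM = dvec, gr = gr_mean, weight = w,
                          residual = resid),
    diagnostics = list(sse = sse(par), rmse = sqrt(mean(resid^2)),
                       high_cv_doses = dvec[which(gr_cv[keep] > cv_bound)],
                       cv_bound = cv_bound, converged = TRUE)
  ), class = "gr_fit")
}

#' Classify platinum sensitivity from a GR50 fit
#'
#' An explant is platinum resistant when GR50 >= `threshold_uM`
#' (48 uM by default, inclusive); a GR50 censored above the dose range
#' counts as resistant.
#'
#' @param gr50 A `gr_fit` object, or a numeric GR50 in uM (`Inf` for
#'   censored).
#' @param threshold_uM Classification threshold (default 48).
#' @return `"sensitive"` or `"resistant"`.
#' @export
classify_platinum <- function(gr50, threshold_uM = 48) {
  g <- if (inherits(gr50, "gr_fit")) gr50$gr50_uM else gr50
  if (!is.numeric(g) || is.na(g)) {
    stop_ddr("a fitted or censored GR50 is required", class = "ddr_schema_error")
  }
  if (g >= threshold_uM) "resistant" else "sensitive"
}

#' @export
print.gr_fit <- function(x, ...) {
  g <- if (x$censored) sprintf("> %g (censored)", x$censor_limit_uM)
       else sprintf("%.3g", x$gr50_uM)
  cat(sprintf("<gr_fit> %s: GR50 = %s uM; GR_inf %.3f, GEC50 %.3g uM, h %.2f\n",
              x$explant_id %||% "", g, x$params[["GR_inf"]],
              x$params[["GEC50"]], x$params[["h"]]))
  invisible(x)
}

#' @export
coef.gr_fit <- function(object, ...) object$params

#' Predict GR values from a fitted curve
#' @param object A `gr_fit`.
#' @param newdata Numeric vector of concentrations (uM); defaults to the
#'   fitted doses.
#' @param ... Unused.
#' @export
predict.gr_fit <- function(object, newdata = NULL, ...) {
  conc <- newdata %||% object$gr_table$dose_uM
  p <- object$params
  out <- gr_sigmoid(conc, p[["GR_inf"]], p[["GEC50"]], p[["h"]])
  out[conc == 0] <- 1
  out
}

#' @export
residuals.gr_fit <- function(object, ...) object$gr_table$residual

#' Plot a fitted GR dose-response curve
#' @param x A `gr_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gr_fit <- function(x, ...) {
  tb <- x$gr_table
  cc <- exp(seq(log(min(tb$dose_uM)), log(max(tb$dose_uM)), length.out = 200))
  graphics::plot(tb$dose_uM, tb$gr, log = "x", xlab = "carboplatin (uM)",
                 ylab = "GR", ylim = range(c(tb$gr, -1, 1)), ...)
  graphics::lines(cc, predict(x, cc))
  graphics::abline(h = 0.5, lty = 3)
  if (!x$censored) graphics::abline(v = x$gr50_uM, lty = 2)
  invisible(x)
}

#' Simulate a single GR viability plate with known curve parameters
#'
#' Generates per-well endpoint counts on the 12-point carboplatin grid
#' from a known GR sigmoid with lognormal measurement noise — the
#' parameter-recovery harness for [fit_gr_curve()].
#'
#' @param gr_inf,gec50,h True curve parameters.
#' @param x0 Seeded cells per well (default 2000).
#' @param growth_doublings Untreated growth over the assay (default 2).
#' @param replicates Wells per dose (default 3).
#' @param sigma Lognormal noise sdlog (default 0.05).
#' @param doses Concentration grid (default [carboplatin_grid()]).
#' @return Data frame suitable for [fit_gr_curve()]; the true GR50 is
#'   attached as attribute `gr50_true`.
#' @export
simulate_gr_plate <- function(gr_inf, gec50, h, x0 = 2000, growth_doublings = 2,
                              replicates = 3, sigma = 0.05,
                              doses = carboplatin_grid()) {
  grid <- expand.grid(dose_uM = doses, replicate = seq_len(replicates))
  gr <- gr_sigmoid(grid$dose_uM, gr_inf, gec50, h)
  gr[grid$dose_uM == 0] <- 1
  xc <- x0 * 2^(log2(gr + 1) * growth_doublings)
  plate <- data.frame(dose_uM = grid$dose_uM, replicate = grid$replicate,
                      count = xc * stats::rlnorm(nrow(grid), 0, sigma), x0 = x0)
  attr(plate, "gr50_true") <- gr50_from_params(gr_inf, gec50, h)
  plate
}
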