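#' Binary survival-horizon labels from outcome records
#'
#' A patient is labelled 1 (progressed/died within the horizon) when the
#' endpoint event occurred at or before `horizon_months`; 0 when follow-up
#' extends past the horizon without the event; and excluded (`NA`, with a
#' censoring note) when follow-up ends before the horizon without an
#' event.
#'
#' @param outcomes Data frame with columns `patient_id`, `pfs_days`,
#'   `os_days`, `pfs_event`, `os_event`.
#' @param endpoint `"PFS"` or `"OS"`.
#' @param horizon_months Horizon in months (months are 30.44 days).
#' @return Named integer vector (0/1/NA) with attribute `"excluded"`
#'   listing censored-before-horizon patient ids.
#' @export
horizon_labels <- function(outcomes, endpoint = c("PFS", "OS"), horizon_months) {
  endpoint <- match.arg(endpoint)
  cols <- if (endpoint == "PFS") c("pfs_days", "pfs_event") else c("os_days", "os_event")
  assert_cols(outcomes, c("patient_id", cols), "outcome")
  days <- outcomes[[cols[1]]]
  event <- as.logical(outcomes[[cols[2]]])
  if (any(days <= 0, na.rm = TRUE)) {
    stop_ddr("survival durations must be positive", class = "ddr_integrity_error")
  }
  horizon <- horizon_months * DAYS_PER_MONTH
  label <- ifelse(event & days <= horizon, 1L,
                  ifelse(days > horizon, 0L, NA_integer_))
  names(label) <- outcomes$patient_id
  attr(label, "excluded") <- outcomes$patient_id[is.na(label)]
  attr(label, "endpoint") <- endpoint
  attr(label, "horizon_months") <- horizon_months
  label
}

#' ROC area under the curve
#'
#' `AUC = P(score_pos > score_neg) + 0.5 * P(tie)` over all
#' positive-negative pairs, computed with the rank (Mann-Whitney) formula,
#' which handles ties exactly.
#'
#' @param scores Numeric decision scores (higher = more positive).
#' @param labels Binary labels (0/1 or logical).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) {
    stop_ddr("scores and labels differ in length", class = "ddr_schema_error")
  }
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop_ddr("both classes must be present to compute an AUC",
             class = "ddr_degenerate_label_error")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

new_class_report <- function(model, ...) {
  structure(c(list(model = model), list(...)), class = "ddr_class_report")
}

#' @export
print.ddr_class_report <- function(x, ...) {
  cat(sprintf("<ddr_class_report> %s (cv: %s) AUC %s; classes %s%s\n",
              x$model, x$cv_scheme %||% "none",
              if (is.na(x$roc_auc)) "NA" else sprintf("%.3f", x$roc_auc),
              paste(x$class_counts, collapse = "/"),
              if (!isTRUE(x$validity_flag)) " [INVALID for partitioned validation]" else ""))
  invisible(x)
}

prepare_xy <- function(features, labels) {
  x <- as.matrix(as.data.frame(features))
  storage.mode(x) <- "double"
  y <- as.integer(as.logical(labels))
  keep <- stats::complete.cases(x) & !is.na(y)
  dropped <- sum(!keep)
  x <- x[keep, , drop = FALSE]; y <- y[keep]
  if (length(unique(y)) < 2) {
    stop_ddr("labels contain a single class", class = "ddr_degenerate_label_error")
  }
  list(x = x, y = y, dropped = dropped)
}

lda_direction <- function(x, y, ridge = 1e-6) {
  mu0 <- colMeans(x[y == 0, , drop = FALSE])
  mu1 <- colMeans(x[y == 1, , drop = FALSE])
  p <- ncol(x)
  pool <- matrix(0, p, p)
  dof <- 0
  for (cls in c(0, 1)) {
    xi <- x[y == cls, , drop = FALSE]
    if (nrow(xi) >= 2) {
      pool <- pool + stats::cov(xi) * (nrow(xi) - 1)
      dof <- dof + nrow(xi) - 1
    }
  }
  S <- pool / max(dof, 1)
  w <- tryCatch({
    if (rcond(S) < 1e-10) stop("singular")
    solve(S, mu1 - mu0)
  }, error = function(e) {
    Sr <- S + diag(ridge * sum(diag(S)) / p + 1e-12, p)
    solve(Sr, mu1 - mu0)
  })
  # standardise so the within-class variance of the discriminant is 1
  s2 <- drop(t(w) %*% S %*% w)
  if (is.finite(s2) && s2 > 0) w <- w / sqrt(s2)
  list(w = w, S = S, mu0 = mu0, mu1 = mu1)
}

#' Two-class linear discriminant classifier
#'
#' Fisher's linear discriminant with pooled within-class covariance,
#' ridge-regularised (`ridge * trace(S) / p` added to the diagonal) when
#' the pooled covariance is singular — common with binary capacity
#' features on small cohorts. Reports standardised discriminant
#' coefficients (unit within-class variance) and the in-sample ROC AUC of
#' the discriminant score, labelled as in-sample.
#'
#' @param features Numeric matrix/data frame (rows = patients). Rows with
#'   missing values are dropped and counted in the report.
#' @param labels Binary labels.
#' @param ridge Ridge factor applied when the pooled covariance is
#'   singular (default 1e-6).
#' @return A `ddr_class_report` with `coefficients`, `scores`,
#'   `roc_auc` (in-sample), `class_counts`, and `validity_flag`
#'   (`FALSE` when the minority class has exactly one member, which rules
#'   out data-partitioned internal validation).
#' @export
fit_lda <- function(features, labels, ridge = 1e-6) {
  d <- prepare_xy(features, labels)
  fit <- lda_direction(d$x, d$y, ridge)
  scores <- drop(d$x %*% fit$w)
  counts <- table(factor(d$y, levels = 0:1))
  new_class_report(
    "LDA",
    coefficients = fit$w,
    scores = scores,
    labels = d$y,
    roc_auc = roc_auc(scores, d$y),
    auc_type = "in_sample",
    cv_scheme = "none",
    class_counts = as.integer(counts),
    n_dropped = d$dropped,
    validity_flag = min(counts) >= 2
  )
}

#' Feed-forward perceptron classifier with repeated restarts
#'
#' Single-hidden-layer perceptron (`nnet`) with logistic activations,
#' hidden size `ceiling((p + 1) / 2)`, trained for `iterations`
#' optimisation steps, restarted `repeats` times from seeded random
#' initialisations. The reported AUC is the mean in-sample AUC over
#' repeats; the per-repeat vector is retained.
#'
#' @inheritParams fit_lda
#' @param iterations Training iterations per repeat (default 200).
#' @param repeats Random-initialisation repeats (default 50).
#' @param seed Master seed for the repeat initialisations.
#' @param decay Weight decay (default 1e-4).
#' @return A `ddr_class_report`; `repeat_aucs` holds all repeats.
#' @export
fit_ann <- function(features, labels, iterations = 200, repeats = 50,
                    seed = 1, decay = 1e-4) {
  d <- prepare_xy(features, labels)
  x <- scale(d$x)
  x[, attr(x, "scaled:scale") == 0] <- 0
  size <- ceiling((ncol(x) + 1) / 2)
  aucs <- numeric(repeats)
  last_prob <- NULL
  for (r in seq_len(repeats)) {
    prob <- with_seed(derive_seed(seed, r), {
      fit <- nnet::nnet(x, d$y, size = size, maxit = iterations, decay = decay,
                        entropy = TRUE, trace = FALSE)
      drop(stats::predict(fit, x))
    })
    if (any(!is.finite(prob))) {
      stop_ddr("non-finite network output: training failure", class = "ddr_fit_error")
    }
    aucs[r] <- roc_auc(prob, d$y)
    last_prob <- prob
  }
  counts <- table(factor(d$y, levels = 0:1))
  new_class_report(
    "aNN",
    roc_auc = mean(aucs),
    repeat_aucs = aucs,
    auc_type = "in_sample_mean_over_repeats",
    scores = last_prob,
    labels = d$y,
    architecture = list(hidden = size, iterations = iterations,
                        repeats = repeats, decay = decay),
    cv_scheme = "none",
    class_counts = as.integer(counts),
    n_dropped = d$dropped,
    validity_flag = min(counts) >= 2
  )
}

#' RBF-kernel support vector machine with tune-grid search
#'
#' Radial-kernel SVM (`e1071::svm`) tuned over a (cost, gamma) grid by
#' seeded inner cross-validation on pooled out-of-fold AUC, then refitted
#' on all rows. When the minority class has fewer than 2 members the tune
#' grid cannot be cross-validated: the report carries
#' `validity_flag = FALSE`, no inner CV is run, and the first grid point
#' is fitted in-sample only.
#'
#' @inheritParams fit_lda
#' @param tune_grid List with numeric `cost` and `gamma` vectors; the
#'   default spans cost 0.25-16 and gamma (0.5, 1, 2)/p.
#' @param inner_k Inner CV folds (default 5, capped at minority size).
#' @param seed Seed for fold assignment.
#' @return A `ddr_class_report` with `best_params` and in-sample AUC.
#' @export
fit_svm_rbf <- function(features, labels, tune_grid = NULL, inner_k = 5, seed = 1) {
  d <- prepare_xy(features, labels)
  p <- ncol(d$x)
  grid <- tune_grid %||% list(cost = c(0.25, 1, 4, 16), gamma = c(0.5, 1, 2) / p)
  if (!length(grid$cost) || !length(grid$gamma)) {
    stop_ddr("tune grid must be non-empty", class = "ddr_tuning_error")
  }
  combos <- expand.grid(cost = grid$cost, gamma = grid$gamma)
  counts <- table(factor(d$y, levels = 0:1))
  yf <- factor(d$y, levels = 0:1)

  # raw decision values; orientation is resolved against the AUC at the
  # call sites (decision-value sign depends on which class svm saw first)
  svm_scores <- function(xtr, ytr, xte, cost, gamma) {
    fit <- e1071::svm(xtr, factor(ytr, levels = 0:1), kernel = "radial",
                      cost = cost, gamma = gamma, scale = FALSE)
    drop(attr(stats::predict(fit, xte, decision.values = TRUE), "decision.values"))
  }

  x <- scale(d$x)
  x[, attr(x, "scaled:scale") == 0] <- 0

  if (min(counts) < 2) {
    sc <- svm_scores(x, d$y, x, combos$cost[1], combos$gamma[1])
    if (roc_auc(sc, d$y) < 0.5) sc <- -sc
    return(new_class_report("SVM_RBF", roc_auc = roc_auc(sc, d$y),
                            auc_type = "in_sample", scores = sc, labels = d$y,
                            best_params = combos[1, ], cv_scheme = "none",
                            class_counts = as.integer(counts),
                            n_dropped = d$dropped, validity_flag = FALSE))
  }

  k <- min(inner_k, min(counts))
  folds <- with_seed(derive_seed(seed, 17), make_folds(d$y, k))
  best <- NULL
  for (i in seq_len(nrow(combos))) {
    oof <- rep(NA_real_, length(d$y))
    ok <- TRUE
    for (f in seq_len(k)) {
      tr <- folds != f
      if (length(unique(d$y[tr])) < 2) { ok <- FALSE; break }
      sc <- tryCatch(svm_scores(x[tr, , drop = FALSE], d$y[tr],
                                x[!tr, , drop = FALSE],
                                combos$cost[i], combos$gamma[i]),
                     error = function(e) NULL)
      if (is.null(sc)) { ok <- FALSE; break }
      oof[!tr] <- sc
    }
    if (!ok) next
    a <- roc_auc(oof, d$y); a <- max(a, 1 - a)
    if (is.null(best) || a > best$auc) best <- list(auc = a, i = i)
  }
  if (is.null(best)) {
    stop_ddr("every tune-grid combination failed", class = "ddr_tuning_error")
  }
  sc <- svm_scores(x, d$y, x, combos$cost[best$i], combos$gamma[best$i])
  if (roc_auc(sc, d$y) < 0.5) sc <- -sc
  new_class_report("SVM_RBF", roc_auc = roc_auc(sc, d$y), auc_type = "in_sample",
                   scores = sc, labels = d$y,
                   best_params = combos[best$i, ],
                   inner_cv_auc = best$auc, cv_scheme = "none",
                   class_counts = as.integer(counts), n_dropped = d$dropped,
                   validity_flag = TRUE)
}

# stratified fold ids in 1..k
make_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Cross-validated classification
#'
#' Trains the requested model on each training partition and pools
#' held-out decision scores into a single out-of-fold ROC AUC. Schemes:
#' `"loocv"`, `list(type = "repeated_kfold", k = , r = )`, and
#' `list(type = "lgocv", p = , r = )` (leave-group-out / Monte Carlo with
#' training fraction `p`). Fold assignments are seeded and returned.
#' When the minority class has fewer than 2 members the scheme is refused
#' (`validity_flag = FALSE`, AUC `NA`).
#'
#' @param model `"lda"`, `"ann"`, or `"svm"`.
#' @param features,labels As in [fit_lda()].
#' @param scheme Scheme name or list (see Details).
#' @param seed Seed for fold assignment and model restarts.
#' @param ... Passed to the underlying fitter (e.g. `repeats` for
#'   `"ann"`; CV defaults to 5 repeats per fold for tractability).
#' @return A `ddr_class_report` with pooled out-of-fold AUC.
#' @export
cross_validate <- function(model = c("lda", "ann", "svm"), features, labels,
                           scheme = "loocv", seed = 1, ...) {
  model <- match.arg(model)
  d <- prepare_xy(features, labels)
  n <- length(d$y)
  counts <- table(factor(d$y, levels = 0:1))
  if (is.character(scheme)) scheme <- list(type = scheme)
  type <- match.arg(scheme$type, c("loocv", "repeated_kfold", "lgocv"))

  if (min(counts) < 2) {
    return(new_class_report(toupper(model), roc_auc = NA_real_,
                            cv_scheme = type, class_counts = as.integer(counts),
                            n_dropped = d$dropped, validity_flag = FALSE,
                            refusal = "minority class has a single member: unsuitable for data-partitioned internal validation"))
  }

  train_score <- function(tr, te, fold_seed) {
    xtr <- d$x[tr, , drop = FALSE]; ytr <- d$y[tr]
    xte <- d$x[te, , drop = FALSE]
    if (length(unique(ytr)) < 2) return(rep(NA_real_, length(te)))
    switch(model,
      lda = {
        fit <- lda_direction(xtr, ytr)
        drop(xte %*% fit$w)
      },
      ann = {
        ctr <- colMeans(xtr); scl <- apply(xtr, 2, stats::sd); scl[scl == 0] <- 1
        xs <- scale(xtr, ctr, scl)
        args <- list(...)
        reps <- args$repeats %||% 5
        iters <- args$iterations %||% 200
        probs <- matrix(0, nrow = length(te), ncol = reps)
        for (r in seq_len(reps)) {
          probs[, r] <- with_seed(derive_seed(fold_seed, r), {
            fit <- nnet::nnet(xs, ytr, size = ceiling((ncol(xs) + 1) / 2),
                              maxit = iters, decay = 1e-4, entropy = TRUE,
                              trace = FALSE)
            drop(stats::predict(fit, scale(xte, ctr, scl)))
          })
        }
        rowMeans(probs)
      },
      svm = {
        ctr <- colMeans(xtr); scl <- apply(xtr, 2, stats::sd); scl[scl == 0] <- 1
        xs <- scale(xtr, ctr, scl)
        fit <- e1071::svm(xs, factor(ytr, levels = 0:1), kernel = "radial",
                          cost = 1, gamma = 1 / ncol(xs), scale = FALSE)
        dv <- drop(attr(stats::predict(fit, scale(xte, ctr, scl),
                                       decision.values = TRUE), "decision.values"))
        # orient decision values toward class 1 using training fit
        dtr <- drop(attr(stats::predict(fit, xs, decision.values = TRUE),
                         "decision.values"))
        if (roc_auc(dtr, ytr) < 0.5) dv <- -dv
        dv
      })
  }

  if (type == "loocv") {
    oof <- vapply(seq_len(n), function(i) {
      train_score(setdiff(seq_len(n), i), i, derive_seed(seed, i))[1]
    }, numeric(1))
    pooled_scores <- oof; pooled_labels <- d$y
    fold_log <- seq_len(n)
  } else if (type == "repeated_kfold") {
    k <- scheme$k %||% 5; r <- scheme$r %||% 3
    if (k > n) stop_ddr("k exceeds n", class = "ddr_scheme_error")
    pooled_scores <- numeric(0); pooled_labels <- integer(0)
    fold_log <- list()
    for (rep_i in seq_len(r)) {
      folds <- with_seed(derive_seed(seed, rep_i), make_folds(d$y, k))
      fold_log[[rep_i]] <- folds
      oof <- rep(NA_real_, n)
      for (f in seq_len(k)) {
        te <- which(folds == f)
        oof[te] <- train_score(which(folds != f), te, derive_seed(seed, rep_i * 100 + f))
      }
      pooled_scores <- c(pooled_scores, oof)
      pooled_labels <- c(pooled_labels, d$y)
    }
  } else { # lgocv
    p_frac <- scheme$p %||% 0.8; r <- scheme$r %||% 25
    pooled_scores <- numeric(0); pooled_labels <- integer(0)
    fold_log <- list()
    for (rep_i in seq_len(r)) {
      tr <- with_seed(derive_seed(seed, 1000 + rep_i), {
        unlist(lapply(unique(d$y), function(cls) {
          idx <- which(d$y == cls)
          sample(idx, max(1, round(p_frac * length(idx))))
        }))
      })
      te <- setdiff(seq_len(n), tr)
      if (!length(te)) next
      fold_log[[rep_i]] <- te
      pooled_scores <- c(pooled_scores, train_score(tr, te, derive_seed(seed, 2000 + rep_i)))
      pooled_labels <- c(pooled_labels, d$y[te])
    }
  }

  ok <- !is.na(pooled_scores)
  auc <- if (length(unique(pooled_labels[ok])) == 2) {
    roc_auc(pooled_scores[ok], pooled_labels[ok])
  } else NA_real_
  new_class_report(toupper(model), roc_auc = auc, auc_type = "out_of_fold",
                   cv_scheme = type, folds = fold_log,
                   n_oof = sum(ok),
                   class_counts = as.integer(counts), n_dropped = d$dropped,
                   validity_flag = TRUE)
}

#' Correlation with significance test
#'
#' Pearson's r or Kendall's tau-b (tie-corrected; exact p-value for small
#' tie-free samples, normal approximation otherwise), via
#' [stats::cor.test()].
#'
#' @param x,y Paired numeric vectors (n >= 3).
#' @param method `"pearson"` or `"kendall_b"`.
#' @return List with `coefficient`, `p_value`, `method`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "kendall_b")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_ddr("need at least 3 paired values", class = "ddr_schema_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_ddr("zero variance: correlation undefined", class = "ddr_undefined_correlation_error")
  }
  ct <- suppressWarnings(stats::cor.test(x, y,
                                         method = if (method == "pearson") "pearson" else "kendall"))
  list(coefficient = unname(ct$estimate), p_value = ct$p.value,
       method = method, n = length(x))
}

#' Group comparison with automatic parametric/nonparametric branching
#'
#' Normality is assessed per group (Shapiro-Wilk, or Kolmogorov-Smirnov
#' for very large groups). When every group is consistent with normality
#' the parametric branch runs (t test for two groups, ANOVA or Welch's
#' ANOVA depending on Bartlett's variance-homogeneity test, with
#' Benjamini-Hochberg-adjusted pairwise t tests post hoc); otherwise the
#' nonparametric branch (Wilcoxon rank-sum or Kruskal-Wallis with
#' Dunn-Sidak-adjusted pairwise comparisons).
#'
#' @param values Numeric vector.
#' @param groups Group labels (>= 2 groups, each with >= 2 members).
#' @param alpha Normality-gate level (default 0.05).
#' @return List recording the branch taken, gate p-values, the omnibus
#'   test, and adjusted post hoc p-values.
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_ddr("need >= 2 groups", class = "ddr_schema_error")
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop_ddr("group(s) with fewer than 2 members: ",
             paste(names(sizes)[sizes < 2], collapse = ", "),
             class = "ddr_degenerate_group_error")
  }
  by_g <- split(values, groups)
  norm_p <- vapply(by_g, function(v) {
    if (stats::sd(v) == 0) return(0)
    if (length(v) <= 5000 && length(v) >= 3) stats::shapiro.test(v)$p.value
    else suppressWarnings(stats::ks.test(scale(v), "pnorm")$p.value)
  }, numeric(1))
  parametric <- all(norm_p > alpha)
  k <- nlevels(groups)
  if (parametric) {
    var_p <- stats::bartlett.test(values, groups)$p.value
    if (k == 2) {
      tt <- stats::t.test(by_g[[1]], by_g[[2]], var.equal = var_p > alpha)
      omnibus <- list(test = if (var_p > alpha) "t" else "welch_t", p_value = tt$p.value)
    } else if (var_p > alpha) {
      fit <- stats::aov(values ~ groups)
      omnibus <- list(test = "anova",
                      p_value = summary(fit)[[1]][["Pr(>F)"]][1])
    } else {
      wt <- stats::oneway.test(values ~ groups)
      omnibus <- list(test = "welch_anova", p_value = wt$p.value)
    }
    ph <- stats::pairwise.t.test(values, groups, p.adjust.method = "BH")$p.value
    adjust <- "BH"
  } else {
    var_p <- NA_real_
    if (k == 2) {
      wt <- suppressWarnings(stats::wilcox.test(by_g[[1]], by_g[[2]]))
      omnibus <- list(test = "wilcoxon_rank_sum", p_value = wt$p.value)
    } else {
      kw <- stats::kruskal.test(values, groups)
      omnibus <- list(test = "kruskal_wallis", p_value = kw$p.value)
    }
    raw <- suppressWarnings(
      stats::pairwise.wilcox.test(values, groups, p.adjust.method = "none")$p.value)
    m <- sum(!is.na(raw))
    ph <- 1 - (1 - raw)^m      # Dunn-Sidak family adjustment
    adjust <- "dunn_sidak"
  }
  list(branch = if (parametric) "parametric" else "nonparametric",
       normality_p = norm_p, variance_p = var_p,
       omnibus = omnibus, posthoc_adjusted = ph, adjust_method = adjust)
}
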