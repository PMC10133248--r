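class_summaries <- function(coords, classes, n_comp = 3) {
  if (is.null(classes)) return(NULL)
  n_comp <- min(n_comp, ncol(coords))
  cls <- factor(classes)
  out <- lapply(levels(cls), function(l) {
    m <- coords[cls == l, seq_len(n_comp), drop = FALSE]
    centroid <- colMeans(m)
    # spheroid radius: RMS distance of class members to the centroid
    radius <- sqrt(mean(rowSums(sweep(m, 2, centroid)^2)))
    list(class = l, centroid = centroid, radius = radius, n = nrow(m))
  })
  names(out) <- levels(cls)
  out
}

#' Principal component analysis of numeric-encoded signatures
#'
#' Standardised PCA (eigendecomposition of the correlation matrix via
#' [stats::prcomp()]): variable loadings, patient scores, explained-
#' variance fractions, and optional per-class centroids with spheroid
#' radii (RMS member distance) in the first three components.
#'
#' @param features Numeric matrix or data frame (rows = patients).
#'   Constant columns are dropped with a warning.
#' @param classes Optional class labels for centroid/spheroid summaries.
#' @param standardize Scale columns to unit variance (default `TRUE`).
#' @return Object of class `ddr_reduction` with `method = "PCA"`,
#'   `scores`, `loadings`, `explained` and `class_summaries`.
#' @export
run_pca <- function(features, classes = NULL, standardize = TRUE) {
  x <- as.matrix(as.data.frame(features))
  storage.mode(x) <- "double"
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop_ddr("PCA needs >= 2 rows and >= 2 columns", class = "ddr_schema_error")
  }
  const <- apply(x, 2, stats::sd) == 0
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = standardize)
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(method = "PCA",
                 scores = fit$x,
                 loadings = fit$rotation,
                 sdev = fit$sdev,
                 explained = expl,
                 center = fit$center, scale = fit$scale,
                 class_summaries = class_summaries(fit$x, classes)),
            class = "ddr_reduction")
}

#' Multiple correspondence analysis of categorical signatures
#'
#' Correspondence analysis of the complete indicator (disjunctive) matrix:
#' SVD of the standardised residuals of the indicator table. Returns row
#' (patient) principal coordinates, column (category) principal
#' coordinates, raw inertia fractions and Benzecri-corrected fractions
#' (reported, not default), plus per-class centroid and spheroid-radius
#' summaries in the first `n_components` dimensions.
#'
#' @param features Data frame of categorical columns (each >= 2 observed
#'   levels; single-level columns are dropped with a warning).
#' @param n_components Components to report (default 3).
#' @param classes Optional class labels for centroid summaries.
#' @return Object of class `ddr_reduction` with `method = "MCA"`.
#' @export
run_mca <- function(features, n_components = 3, classes = NULL) {
  df <- as.data.frame(features, stringsAsFactors = FALSE)
  df[] <- lapply(df, function(col) factor(as.character(col)))
  single <- vapply(df, nlevels, integer(1)) < 2
  if (any(single)) {
    warning("dropping single-level column(s): ",
            paste(names(df)[single], collapse = ", "))
    df <- df[, !single, drop = FALSE]
  }
  if (!ncol(df)) stop_ddr("no categorical columns with >= 2 levels",
                          class = "ddr_schema_error")
  n <- nrow(df); Q <- ncol(df)
  # complete indicator matrix
  Z <- do.call(cbind, lapply(names(df), function(v) {
    m <- stats::model.matrix(~ 0 + df[[v]])
    colnames(m) <- paste(v, levels(df[[v]]), sep = "=")
    m
  }))
  P <- Z / sum(Z)
  r <- rowSums(P); cmass <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - tcrossprod(r, cmass)) %*% diag(1 / sqrt(cmass))
  sv <- svd(S)
  pos <- sv$d > 1e-12
  d <- sv$d[pos]
  row_coord <- diag(1 / sqrt(r)) %*% sv$u[, pos, drop = FALSE] %*% diag(d, sum(pos))
  col_coord <- diag(1 / sqrt(cmass)) %*% sv$v[, pos, drop = FALSE] %*% diag(d, sum(pos))
  rownames(row_coord) <- rownames(df)
  rownames(col_coord) <- colnames(Z)
  colnames(row_coord) <- colnames(col_coord) <- paste0("Dim", seq_len(sum(pos)))
  inertia <- d^2
  expl <- inertia / sum(inertia)
  # Benzecri correction: only eigenvalues above 1/Q carry signal
  lam <- inertia
  benz <- ifelse(lam > 1 / Q, (Q / (Q - 1))^2 * (lam - 1 / Q)^2, 0)
  benz_frac <- if (sum(benz) > 0) benz / sum(benz) else benz
  k <- min(n_components, ncol(row_coord))
  structure(list(method = "MCA",
                 scores = row_coord[, seq_len(k), drop = FALSE],
                 all_scores = row_coord,
                 column_coords = col_coord,
                 explained = expl,
                 explained_benzecri = benz_frac,
                 singular_values = d,
                 n_components = k,
                 class_summaries = class_summaries(row_coord, classes, k)),
            class = "ddr_reduction")
}

#' @export
print.ddr_reduction <- function(x, ...) {
  k <- min(3, length(x$explained))
  cat(sprintf("<ddr_reduction> %s: first %d components explain %s\n",
              x$method, k,
              paste(sprintf("%.1f%%", 100 * x$explained[seq_len(k)]), collapse = ", ")))
  if (!is.null(x$class_summaries)) {
    for (s in x$class_summaries) {
      cat(sprintf("  class %s: n=%d, spheroid radius %.3f\n", s$class, s$n, s$radius))
    }
  }
  invisible(x)
}

#' @export
plot.ddr_reduction <- function(x, ...) {
  graphics::plot(x$scores[, 1], x$scores[, 2],
                 xlab = sprintf("%s 1 (%.1f%%)", x$method, 100 * x$explained[1]),
                 ylab = sprintf("%s 2 (%.1f%%)", x$method, 100 * x$explained[2]), ...)
  invisible(x)
}
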