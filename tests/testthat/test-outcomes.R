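test_that("horizon labels respect events, follow-up and censoring", {
  outcomes <- data.frame(
    patient_id = c("A", "B", "C", "D"),
    pfs_days = c(400, 100, 120, 500), os_days = c(500, 300, 200, 600),
    pfs_event = c(FALSE, TRUE, FALSE, TRUE),
    os_event = c(FALSE, FALSE, FALSE, TRUE))
  lab12 <- horizon_labels(outcomes, "PFS", 12)
  expect_equal(unname(lab12[["A"]]), 0L)        # follow-up past horizon
  expect_equal(unname(lab12[["B"]]), 1L)        # progressed inside horizon
  expect_true(is.na(lab12[["C"]]))              # censored before horizon
  expect_equal(attr(lab12, "excluded"), "C")
  lab6 <- horizon_labels(outcomes, "PFS", 6)
  expect_equal(unname(lab6[["B"]]), 1L)

  bad <- outcomes; bad$pfs_days[1] <- -2
  expect_error(horizon_labels(bad, "PFS", 12), class = "ddr_integrity_error")
})

test_that("ROC AUC matches hand-computable cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_error(roc_auc(1:3, c(1, 1, 1)), class = "ddr_degenerate_label_error")
})

test_that("ROC AUC equals brute-force pair counting and is anti-symmetric", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # ties likely
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(roc_auc(scores, labels), auc_bruteforce(scores, labels))
    expect_equal(roc_auc(scores, 1 - labels), 1 - roc_auc(scores, labels))
  }
  skip_if_not_installed("pROC")
  scores <- c(0.9, 0.8, 0.8, 0.4, 0.2, 0.1)
  labels <- c(1, 0, 1, 1, 0, 0)
  ref <- as.numeric(suppressMessages(pROC::auc(labels, scores, direction = "<")))
  expect_equal(roc_auc(scores, labels), ref)
})

test_that("LDA direction matches the closed form and the reference fit", {
  set.seed(5)
  n <- 200
  x <- matrix(rnorm(n * 3), n, 3) %*% matrix(c(1, .4, 0, .4, 1, .2, 0, .2, 1), 3)
  y <- rep(0:1, each = n / 2)
  x[y == 1, ] <- x[y == 1, ] + rep(c(1, 0.5, -0.5), each = n / 2)
  rep_lda <- fit_lda(x, y)
  # closed-form oracle: pooled Sigma^{-1} (mu1 - mu0)
  S <- (cov(x[y == 0, ]) * (n / 2 - 1) + cov(x[y == 1, ]) * (n / 2 - 1)) / (n - 2)
  w_oracle <- solve(S, colMeans(x[y == 1, ]) - colMeans(x[y == 0, ]))
  cosine <- sum(rep_lda$coefficients * w_oracle) /
    sqrt(sum(rep_lda$coefficients^2) * sum(w_oracle^2))
  expect_equal(cosine, 1, tolerance = 1e-8)
  # cross-check against MASS::lda scaling direction
  m <- MASS::lda(x, grouping = factor(y))
  cos_mass <- abs(sum(rep_lda$coefficients * m$scaling) /
                    sqrt(sum(rep_lda$coefficients^2) * sum(m$scaling^2)))
  expect_equal(cos_mass, 1, tolerance = 1e-8)
})

test_that("LDA separates separable data and centres at 0.5 under permutation", {
  set.seed(6)
  x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 4), 20))
  y <- rep(0:1, each = 20)
  expect_equal(fit_lda(x, y)$roc_auc, 1.0)

  # in-sample AUC under permuted labels: centred near 0.5 up to the
  # small-sample optimism of an in-sample fit
  n <- 400
  xn <- matrix(rnorm(n * 2), n, 2)
  perm_aucs <- replicate(50, fit_lda(xn, sample(rep(0:1, each = n / 2)))$roc_auc)
  expect_lt(abs(mean(perm_aucs) - 0.5), 0.06)
})

test_that("LDA handles singular pooled covariance via the ridge and flags n-of-1", {
  x <- cbind(c(0, 0, 0, 1, 1, 1), c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 1, 1, 1))
  y <- c(0, 0, 0, 1, 1, 1)   # within-group constant features: singular S
  rep_lda <- fit_lda(x, y)
  expect_equal(rep_lda$roc_auc, 1.0)
  one_min <- fit_lda(rbind(x, c(0, 1, 1)), c(y[1:5], 1, 0))
  expect_false(fit_lda(x[c(1:5, 6), ], c(0, 0, 0, 0, 0, 1))$validity_flag)
  expect_error(fit_lda(x, rep(1, 6)), class = "ddr_degenerate_label_error")
})

test_that("the perceptron network is deterministic per seed and learns separable data", {
  set.seed(8)
  x <- rbind(matrix(rnorm(30, 0), 15), matrix(rnorm(30, 4), 15))
  y <- rep(0:1, each = 15)
  r1 <- fit_ann(x, y, repeats = 10, seed = 42)
  r2 <- fit_ann(x, y, repeats = 10, seed = 42)
  expect_identical(r1$repeat_aucs, r2$repeat_aucs)
  expect_equal(r1$roc_auc, 1.0)
  expect_length(r1$repeat_aucs, 10)

  xn <- matrix(rnorm(200), 100, 2)
  yn <- rep(0:1, 50)
  null_auc <- fit_ann(xn, yn, repeats = 5, seed = 1)$roc_auc
  expect_gt(null_auc, 0.3); expect_lt(null_auc, 0.85)  # in-sample optimism allowed
})

test_that("the RBF SVM solves XOR geometry and guards n-of-1 minorities", {
  set.seed(9)
  n <- 25
  xor <- rbind(cbind(rnorm(n, 0, .3), rnorm(n, 0, .3)),
               cbind(rnorm(n, 3, .3), rnorm(n, 3, .3)),
               cbind(rnorm(n, 0, .3), rnorm(n, 3, .3)),
               cbind(rnorm(n, 3, .3), rnorm(n, 0, .3)))
  y <- rep(c(0, 0, 1, 1), each = n)
  expect_gt(fit_svm_rbf(xor, y, seed = 2)$roc_auc, 0.9)

  x <- rbind(matrix(rnorm(30, 0), 15), matrix(rnorm(30, 4), 15))
  expect_equal(fit_svm_rbf(x, rep(0:1, each = 15), seed = 3)$roc_auc, 1.0)

  x1 <- matrix(rnorm(20), 10, 2)
  guard <- fit_svm_rbf(x1, c(rep(0, 9), 1))
  expect_false(guard$validity_flag)
  expect_error(fit_svm_rbf(x, rep(0:1, each = 15), tune_grid = list(cost = numeric(0), gamma = 1)),
               class = "ddr_tuning_error")
})

test_that("cross-validation schemes partition as specified", {
  set.seed(10)
  x <- rbind(matrix(rnorm(16, 0), 8), matrix(rnorm(16, 4), 8))
  y <- rep(0:1, each = 8)
  loo <- cross_validate("lda", x, y, "loocv", seed = 1)
  expect_equal(loo$n_oof, 16)
  expect_equal(loo$roc_auc, 1.0)

  lg1 <- cross_validate("lda", x, y, list(type = "lgocv", p = 0.8, r = 20), seed = 7)
  lg2 <- cross_validate("lda", x, y, list(type = "lgocv", p = 0.8, r = 20), seed = 7)
  expect_identical(lg1$roc_auc, lg2$roc_auc)

  xx <- rbind(matrix(rnorm(100, 0), 50), matrix(rnorm(100, 4), 50))
  yy <- rep(0:1, each = 50)
  rk <- cross_validate("lda", xx, yy, list(type = "repeated_kfold", k = 5, r = 2), seed = 3)
  expect_gte(rk$roc_auc, 0.95)

  expect_error(cross_validate("lda", x, y, list(type = "repeated_kfold", k = 40)),
               class = "ddr_scheme_error")
})

test_that("a single-member minority class always refuses partitioned validation", {
  x <- matrix(rnorm(20), 10, 2)
  y <- c(rep(0, 9), 1)
  for (m in c("lda", "ann", "svm")) {
    ref <- cross_validate(m, x, y, "loocv")
    expect_false(ref$validity_flag)
    expect_true(is.na(ref$roc_auc))
    expect_match(ref$refusal, "single member")
  }
})

test_that("correlations match hand-derived values", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, x, "pearson")$coefficient, 1.0)
  expect_equal(correlate(x, rev(x), "kendall_b")$coefficient, -1.0)
  # 2x2 table with cells (1, 8, 4, 4): tau-b = -28 / sqrt(4320)
  ros <- rep(c(1, 1, 0, 0), c(1, 8, 4, 4))
  mito <- rep(c(1, 0, 1, 0), c(1, 8, 4, 4))
  expect_equal(correlate(ros, mito, "kendall_b")$coefficient, -28 / sqrt(4320),
               tolerance = 1e-12)
  expect_error(correlate(x, rep(1, 5)), class = "ddr_undefined_correlation_error")
})

test_that("tau-b equals brute-force concordance counting and the phi identity", {
  set.seed(14)
  for (i in 1:50) {
    n <- sample(5:25, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(correlate(x, y, "kendall_b")$coefficient, tau_b_bruteforce(x, y),
                 tolerance = 1e-12)
  }
  # phi identity on random 2x2 tables
  for (i in 1:200) {
    cells <- rmultinom(1, sample(20:60, 1), rep(0.25, 4))[, 1] + 1
    a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
    x <- rep(c(1, 1, 0, 0), cells); y <- rep(c(1, 0, 1, 0), cells)
    phi <- (a * d - b * cc) / sqrt((a + b) * (cc + d) * (a + cc) * (b + d))
    expect_equal(correlate(x, y, "kendall_b")$coefficient, phi, tolerance = 1e-12)
  }
})

test_that("group comparison branches on normality and reports adjusted p-values", {
  set.seed(15)
  g <- rep(c("a", "b"), each = 50)
  sep <- compare_groups(c(rnorm(50, 0), rnorm(50, 3)), g)
  expect_equal(sep$branch, "parametric")
  expect_lt(sep$omnibus$p_value, 0.001)

  same <- compare_groups(c(rnorm(50), rnorm(50)), g)
  expect_gt(same$omnibus$p_value, 0.001)

  heavy_branches <- replicate(20, {
    compare_groups(c(rcauchy(40), rcauchy(40)), g[1:80])$branch
  })
  expect_gt(mean(heavy_branches == "nonparametric"), 0.8)

  three <- compare_groups(rnorm(60), rep(c("a", "b", "c"), each = 20))
  expect_true(is.matrix(three$posthoc_adjusted))
  expect_error(compare_groups(rnorm(5), c("a", "a", "a", "a", "b")),
               class = "ddr_degenerate_group_error")
})
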