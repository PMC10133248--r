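test_that("PCA recovers degenerate and isotropic structure", {
  x <- cbind(a = 1:10, b = 2 * (1:10))
  red <- run_pca(x)
  expect_equal(red$explained[1], 1.0, tolerance = 1e-12)

  set.seed(16)
  iso <- matrix(rnorm(2000 * 5), 2000, 5)
  red_iso <- run_pca(iso)
  expect_true(all(abs(red_iso$explained - 0.2) < 0.03))
})

test_that("PCA reconstructs its input when all components are retained", {
  set.seed(17)
  x <- matrix(rnorm(100), 20, 5)
  red <- run_pca(x, standardize = FALSE)
  recon <- red$scores %*% t(red$loadings)
  recon <- sweep(recon, 2, red$center, "+")
  expect_lt(max(abs(recon - x)), 1e-8)
})

test_that("PCA scree is invariant to orthogonal rotation of the input", {
  set.seed(18)
  x <- matrix(rnorm(300), 60, 5) %*% diag(c(3, 2, 1, 1, 0.5))
  q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  expect_equal(run_pca(x, standardize = FALSE)$explained,
               run_pca(x %*% q, standardize = FALSE)$explained, tolerance = 1e-10)
})

test_that("PCA drops constant columns with a warning", {
  x <- cbind(a = rnorm(10), b = rnorm(10), c = 1)
  expect_warning(red <- run_pca(x), "constant")
  expect_equal(ncol(red$loadings), 2)
  expect_error(run_pca(x[, 1, drop = FALSE]), class = "ddr_schema_error")
})

test_that("MCA places duplicated columns' categories at identical coordinates", {
  set.seed(19)
  a <- sample(c("x", "y"), 40, replace = TRUE)
  df <- data.frame(a = a, b = a, c = sample(c("u", "v"), 40, replace = TRUE))
  red <- run_mca(df)
  cc <- red$column_coords
  expect_equal(unname(cc["a=x", ]), unname(cc["b=x", ]), tolerance = 1e-10)
  expect_equal(unname(cc["a=y", ]), unname(cc["b=y", ]), tolerance = 1e-10)
})

test_that("MCA row coordinates survive label renaming and column reordering", {
  set.seed(20)
  df <- data.frame(p = sample(c("comp", "def"), 30, replace = TRUE),
                   q = sample(c("res", "sens"), 30, replace = TRUE),
                   r = sample(c("lo", "mid", "hi"), 30, replace = TRUE))
  base <- run_mca(df)$all_scores
  renamed <- df
  renamed$p <- ifelse(df$p == "comp", "AAA", "BBB")
  ren <- run_mca(renamed)$all_scores
  reord <- run_mca(df[, c("r", "p", "q")])$all_scores
  align <- function(m, ref) {
    for (j in seq_len(ncol(m))) if (sum(m[, j] * ref[, j]) < 0) m[, j] <- -m[, j]
    m
  }
  expect_equal(align(ren, base), base, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(align(reord, base), base, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("MCA separates disjoint category patterns into distinct spheroids", {
  n <- 20
  df <- data.frame(
    a = rep(c("x", "y"), each = n),
    b = rep(c("u", "v"), each = n),
    c = rep(c("p", "q"), each = n)
  )
  # break ties with one noisy column so the solution is unique
  set.seed(22)
  df$d <- sample(c("m", "n"), 2 * n, replace = TRUE)
  red <- run_mca(df, classes = rep(c("g1", "g2"), each = n))
  cs <- red$class_summaries
  sep <- sqrt(sum((cs$g1$centroid - cs$g2$centroid)^2))
  expect_gt(sep, cs$g1$radius + cs$g2$radius)
})

test_that("the dominant association drives MCA component 1", {
  set.seed(23)
  a <- rep(c("x", "y"), each = 15)
  df <- data.frame(a = a, b = a, c = sample(c("u", "v"), 30, replace = TRUE))
  red <- run_mca(df)
  d1 <- red$scores[, 1]
  expect_true(max(d1[a == "x"]) < min(d1[a == "y"]) ||
                min(d1[a == "x"]) > max(d1[a == "y"]))
})

test_that("MCA inertia fractions are valid and Benzecri-corrected fractions reported", {
  set.seed(24)
  df <- data.frame(a = sample(c("x", "y"), 40, TRUE),
                   b = sample(c("u", "v", "w"), 40, TRUE))
  red <- run_mca(df)
  expect_true(all(red$explained >= 0))
  expect_lte(sum(red$explained), 1 + 1e-10)
  expect_true(all(red$explained_benzecri >= 0))
  expect_lte(sum(red$explained_benzecri), 1 + 1e-10)
  expect_warning(run_mca(data.frame(a = df$a, z = "const")), "single-level")
})
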