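test_that("comet condition summaries report medians, IQRs and counts", {
  cs <- comet_condition_summary(make_comet(5, 5, 5, 5))
  expect_equal(unname(cs$medians), rep(5, 4))
  expect_equal(unname(cs$iqrs), rep(0, 4))
  expect_equal(unname(cs$counts), rep(600L, 4))

  # order-statistic check against a uniform condition
  tab <- make_comet(5, 5, 5, 5, n = 4000)
  set.seed(1)
  tab$tail_pct_dna[tab$condition == "3_assault"] <- runif(4000, 0, 100)
  cs <- comet_condition_summary(tab)
  expect_lt(abs(cs$medians[["3_assault"]] - 50), 3)
  expect_lt(abs(cs$iqrs[["3_assault"]] - 50), 4)
})

test_that("comet shortfall errors name only the deficient conditions", {
  tab <- make_comet(5, 6, 20, 45, n = 600)
  sub <- tab[!(tab$condition != "3_assault" & tab$comet_id == 600), ]  # 599 elsewhere
  expect_silent(comet_condition_summary(sub))                          # >= 500 everywhere
  err <- tryCatch(comet_condition_summary(sub, min_comets = 600), error = identity)
  expect_s3_class(err, "ddr_partial_assay_error")
  expect_false(grepl("3_assault", conditionMessage(err)))
  expect_error(comet_condition_summary(tab[tab$condition != "2_blockade", ]),
               class = "ddr_partial_assay_error")
})

test_that("SSB repair fraction contrasts blockade with free recovery", {
  R <- function(m) score_ssb_pathway(comet_condition_summary(
    make_comet(m[1], m[2], m[3], m[4])))
  full <- R(c(5, 6, 5, 45))
  expect_equal(full$score, 1.0)
  expect_equal(full$state, "competent")

  none <- R(c(5, 6, 45, 45))
  expect_equal(none$score, 0.0)
  expect_equal(none$state, "defective")

  half <- R(c(5, 6, 25, 45))
  expect_equal(half$score, 0.5)
  expect_equal(half$state, "competent")  # inclusive default threshold

  expect_equal(full$evidence$blockade_shift, 1)
})

test_that("SSB scoring fails QC without induced damage", {
  no_damage <- score_ssb_pathway(comet_condition_summary(make_comet(5, 6, 5, 8)))
  expect_false(no_damage$qc_pass)
  expect_true(is.na(no_damage$state))
  assault_fail <- score_ssb_pathway(comet_condition_summary(make_comet(20, 21, 15, 10)))
  expect_false(assault_fail$qc_pass)
})

test_that("SSB scoring is monotone in residual damage m3", {
  prev_comp <- TRUE
  for (m3 in seq(5, 45, by = 5)) {
    call <- score_ssb_pathway(comet_condition_summary(make_comet(5, 6, m3, 45)))
    comp <- call$state == "competent"
    # once defective, raising m3 further must never restore competence
    if (!prev_comp) expect_false(comp)
    prev_comp <- comp
  }
})

test_that("comet scoring is invariant to record relabelling", {
  tab <- make_comet(5, 6, 25, 45)
  perm <- tab[sample(nrow(tab)), ]
  perm$comet_id <- seq_len(nrow(perm))
  expect_equal(score_ssb_pathway(comet_condition_summary(perm))$score,
               score_ssb_pathway(comet_condition_summary(tab))$score)
})

test_that("MMR calls require high-impact panel variants with annotator agreement", {
  v <- function(gene, snpeff, vep) data.frame(
    explant_id = "E1", gene = gene, impact_snpeff = snpeff, impact_vep = vep,
    consequence = "x", stringsAsFactors = FALSE)

  hit <- score_mmr(v("MLH1", "HIGH", "HIGH"))
  expect_equal(hit$state, "defective")
  expect_equal(hit$score, 1)

  benign <- score_mmr(rbind(v("MSH2", "MODERATE", "MODERATE"), v("PMS2", "LOW", "LOW")))
  expect_equal(benign$state, "competent")
  expect_equal(benign$score, 0)

  # mode semantics
  split_call <- v("MLH1", "HIGH", "MODIFIER")
  expect_equal(score_mmr(split_call, mode = "intersect")$state, "competent")
  expect_equal(score_mmr(split_call, mode = "union")$state, "defective")

  # off-panel HIGH/HIGH does not qualify
  expect_equal(score_mmr(v("TP53", "HIGH", "HIGH"))$state, "competent")

  expect_error(score_mmr(v("MLH1", "SEVERE", "HIGH")), class = "ddr_schema_error",
               regexp = "MLH1")
})

test_that("MMR rule agrees with the exhaustive impact-pair table", {
  lv <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
  for (a in lv) for (b in lv) {
    rec <- data.frame(explant_id = "E1", gene = "MSH6", impact_snpeff = a,
                      impact_vep = b, consequence = "x", stringsAsFactors = FALSE)
    expect_equal(score_mmr(rec, "intersect")$state,
                 if (a == "HIGH" && b == "HIGH") "defective" else "competent")
    expect_equal(score_mmr(rec, "union")$state,
                 if (a == "HIGH" || b == "HIGH") "defective" else "competent")
  }
})

test_that("the default panel has 22 genes and custom panels load from file", {
  expect_length(mmr_panel(), 22)
  f <- withr::local_tempfile(lines = c("# custom", "GENEA", "GENEB"))
  expect_equal(mmr_panel(f), c("GENEA", "GENEB"))
})
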