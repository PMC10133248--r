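test_that("explant assembly computes aggregate competence sums", {
  all_comp <- make_sig()
  expect_equal(all_comp$dsb_competence, 2)
  expect_equal(all_comp$ssb_competence, 3)
  expect_equal(all_comp$total_competence, 5)

  hrd <- make_sig(c(HR = "defective", NHEJ = "competent", BER = "competent",
                    NER = "competent", MMR = "competent"))
  expect_equal(hrd$dsb_competence, 1)
  expect_equal(hrd$total_competence, 4)
})

test_that("QC-failed calls propagate as missing, not imputed", {
  calls <- list(make_call("HR", "competent"), make_call("NHEJ", "competent"),
                make_call("BER", "competent"),
                ddr_call("NER", NA_real_, NA, qc_pass = FALSE),
                make_call("MMR", "competent"))
  sig <- assemble_explant(calls, explant_id = "E1")
  expect_equal(sig$ssb_competence, 2)
  expect_true(sig$missing_flag)
  expect_true(is.na(sig$states[["NER"]]))
})

test_that("assembly rejects duplicate or missing pathways", {
  calls <- list(make_call("HR", "competent"), make_call("HR", "defective"),
                make_call("BER", "competent"), make_call("NER", "competent"),
                make_call("MMR", "competent"))
  expect_error(assemble_explant(calls), class = "ddr_schema_error")
  expect_error(assemble_explant(calls[3:5]), class = "ddr_schema_error")
})

test_that("single-explant aggregation is the identity on states", {
  e <- make_sig(c(HR = "defective", NHEJ = "competent", BER = "competent",
                  NER = "defective", MMR = "competent"), platinum = "resistant")
  p <- aggregate_patient(list(e))
  expect_equal(p$states, e$states)
  expect_equal(p$platinum_class, "resistant")
  expect_equal(p$total_competence, e$total_competence)
  expect_false(p$heterogeneity_flag)
})

test_that("merge strategies resolve discordance as documented", {
  comp <- make_sig(explant = "E1")
  def <- make_sig(c(HR = "defective", NHEJ = "competent", BER = "competent",
                    NER = "competent", MMR = "competent"), explant = "E2")

  dd <- aggregate_patient(list(comp, def), strategy = "defective_dominant")
  expect_equal(unname(dd$states[["HR"]]), "defective")
  expect_true(dd$heterogeneity_flag)

  maj <- aggregate_patient(list(comp, comp, def), strategy = "majority")
  expect_equal(unname(maj$states[["HR"]]), "competent")
  # ties resolve defective
  tie <- aggregate_patient(list(comp, def), strategy = "majority")
  expect_equal(unname(tie$states[["HR"]]), "defective")

  wc <- aggregate_patient(list(comp, def), strategy = "worst_case")
  expect_equal(unname(wc$states[["HR"]]), "defective")
  expect_equal(unname(wc$scores[["HR"]]), 1)  # worst-case numeric = min capacity

  wm <- aggregate_patient(list(comp, def), strategy = "weighted_mean")
  expect_equal(unname(wm$scores[["HR"]]), 2)  # mean of fold 3 and 1
  expect_equal(unname(wm$states[["HR"]]), "competent")  # inclusive threshold at 2
})

test_that("all-pairs discordance handling matches the rule table", {
  for (s1 in c("competent", "defective")) for (s2 in c("competent", "defective")) {
    e1 <- make_sig(c(HR = s1, NHEJ = "competent", BER = "competent",
                     NER = "competent", MMR = "competent"), explant = "E1")
    e2 <- make_sig(c(HR = s2, NHEJ = "competent", BER = "competent",
                     NER = "competent", MMR = "competent"), explant = "E2")
    p <- aggregate_patient(list(e1, e2))
    expect_equal(unname(p$states[["HR"]]),
                 if (s1 == "defective" || s2 == "defective") "defective" else "competent")
    expect_equal(p$heterogeneity_flag, s1 != s2)
  }
})

test_that("aggregation is permutation-invariant and guards patient identity", {
  e1 <- make_sig(explant = "E1"); e2 <- make_sig(c(
    HR = "defective", NHEJ = "defective", BER = "competent",
    NER = "competent", MMR = "defective"), platinum = "resistant", explant = "E2")
  for (st in c("defective_dominant", "majority", "worst_case", "weighted_mean")) {
    a <- aggregate_patient(list(e1, e2), strategy = st)
    b <- aggregate_patient(list(e2, e1), strategy = st)
    expect_equal(a$states, b$states)
    expect_equal(a$scores, b$scores)
  }
  other <- make_sig(explant = "E9", patient = "P2")
  expect_error(aggregate_patient(list(e1, other)), class = "ddr_integrity_error")
  expect_error(aggregate_patient(list()), class = "ddr_integrity_error")
})

test_that("signature JSON serialisation round-trips field-exactly", {
  sig <- make_sig(c(HR = "defective", NHEJ = "competent", BER = "competent",
                    NER = "defective", MMR = "competent"), platinum = "resistant")
  sig$gr50_uM <- 123.456789012345
  back <- signature_from_json(signature_to_json(sig))
  expect_s3_class(back, "explant_signature")
  expect_identical(back$states, sig$states)
  expect_identical(back$platinum_class, sig$platinum_class)
  expect_equal(back$gr50_uM, sig$gr50_uM, tolerance = 0)
  expect_equal(back$total_competence, sig$total_competence)

  p <- aggregate_patient(list(sig))
  back_p <- signature_from_json(signature_to_json(p))
  expect_s3_class(back_p, "patient_signature")
  expect_identical(back_p$states, p$states)
  expect_equal(back_p$heterogeneity_flag, p$heterogeneity_flag)
})
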