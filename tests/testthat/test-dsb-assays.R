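test_that("HR scoring applies the twofold Rad51 rule under gamma-H2AX QC", {
  # sufficient assault (10 vs 4) and exactly twofold Rad51 induction
  call <- score_hr(make_foci(4, 10, 3, 6))
  expect_true(call$qc_pass)
  expect_equal(call$score, 2.0)
  expect_equal(call$state, "competent")

  # no Rad51 induction
  call <- score_hr(make_foci(4, 10, 3, 3))
  expect_equal(call$score, 1.0)
  expect_equal(call$state, "defective")

  # insufficient assault: gamma-H2AX ratio 1.5 fails QC, state undefined
  call <- score_hr(make_foci(4, 6, 3, 9))
  expect_false(call$qc_pass)
  expect_true(is.na(call$state))
})

test_that("HR scoring degrades to QC failure, not an exception", {
  few <- make_foci(4, 10, 3, 6, n = 10)
  expect_false(score_hr(few)$qc_pass)
  one_cond <- make_foci(4, 10, 3, 6)
  one_cond <- one_cond[one_cond$condition == "control", ]
  expect_false(score_hr(one_cond)$qc_pass)
})

test_that("HR score is a ratio: order- and scale-invariant", {
  foci <- make_foci(4, 10, 3, 6)
  shuffled <- foci[rev(seq_len(nrow(foci))), ]
  expect_equal(score_hr(shuffled)$score, score_hr(foci)$score)
  scaled <- foci
  scaled$rad51_foci <- scaled$rad51_foci * 5L
  scaled$gH2AX_foci <- scaled$gH2AX_foci * 5L
  expect_equal(score_hr(scaled)$score, score_hr(foci)$score)
})

test_that("reporter conformation scoring: ratio, clamp and basal detection", {
  ev <- make_events(c(blunt = 0.12, overhang_5to3 = 0, overhang_3to5 = 0.5),
                    control_rate = 0.4)
  res <- score_nhej_condition(ev, "blunt")
  expect_equal(res$repair_fraction, 0.3)
  expect_equal(res$ordinal, 2L)

  res0 <- score_nhej_condition(ev, "overhang_5to3")
  expect_equal(res0$repair_fraction, 0)
  expect_equal(res0$ordinal, 0L)

  res1 <- score_nhej_condition(ev, "overhang_3to5")
  expect_equal(res1$repair_fraction, 1)  # rate >= control clamps to 1
  expect_equal(res1$ordinal, 3L)
})

test_that("reporter scoring errors are specific", {
  ev <- make_events(c(blunt = 0.12, overhang_5to3 = 0.1, overhang_3to5 = 0.1),
                    control_rate = 0)
  expect_error(score_nhej_condition(ev, "blunt"), class = "ddr_transfection_error")
  ev2 <- make_events(c(blunt = 0.12, overhang_5to3 = 0.1, overhang_3to5 = 0.1))
  expect_error(score_nhej_condition(ev2, "blunt", min_events = 10000),
               class = "ddr_partial_assay_error")
  missing <- ev2[ev2$conformation != "overhang_3to5", ]
  expect_error(score_nhej(missing), class = "ddr_partial_assay_error",
               regexp = "overhang_3to5")
})

test_that("NHEJ integration sums ordinals and applies the two-conformation rule", {
  ev <- make_events(c(blunt = 0.6, overhang_5to3 = 0.3, overhang_3to5 = 0.25),
                    control_rate = 1.0)
  call <- score_nhej(ev)
  expect_equal(call$score, 7)   # ordinals 3, 2, 2
  expect_equal(call$state, "competent")

  ev0 <- make_events(c(blunt = 0.01, overhang_5to3 = 0.01, overhang_3to5 = 0.01),
                     control_rate = 1.0)
  call0 <- score_nhej(ev0)
  expect_equal(call0$score, 0)
  expect_equal(call0$state, "defective")

  # single-conformation repair is insufficient
  ev1 <- make_events(c(blunt = 0.6, overhang_5to3 = 0.01, overhang_3to5 = 0.01),
                     control_rate = 1.0)
  call1 <- score_nhej(ev1)
  expect_equal(call1$score, 3)
  expect_equal(call1$state, "defective")
})

test_that("ordinal integration matches exhaustive enumeration and is monotone", {
  triples <- expand.grid(a = 0:3, b = 0:3, c = 0:3)
  for (i in seq_len(nrow(triples))) {
    o <- as.integer(triples[i, ])
    res <- nhej_integrate(o)
    # independent oracle: direct rule re-derivation
    expect_equal(res$score, o[1] + o[2] + o[3])
    expect_equal(res$state,
                 if ((o[1] >= 2) + (o[2] >= 2) + (o[3] >= 2) >= 2) "competent" else "defective")
    # raising any ordinal never flips competent -> defective
    for (j in 1:3) {
      if (o[j] < 3) {
        o2 <- o; o2[j] <- o2[j] + 1L
        if (res$state == "competent") {
          expect_equal(nhej_integrate(o2)$state, "competent")
        }
      }
    }
  }
})
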