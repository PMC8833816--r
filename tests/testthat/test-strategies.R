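test_that("a conclusive simple-rules call overrides the fallback", {
  # IOTA benign but ROMA clearly high: IOTA wins
  rec <- make_record(b_unilocular = 1L, he4 = 1000, ca125 = 500)
  rc <- apply_strategy(rec, "IOTA_ROMA")
  expect_equal(rc$call, "low")
  expect_false(rc$fallback_used)
  # but ROMA alone calls it high
  expect_equal(apply_strategy(rec, "ROMA_ALONE")$call, "high")
})

test_that("inconclusive masses delegate to the strategy's fallback", {
  rec <- make_record(expert_call = "malignant")
  rc <- apply_strategy(rec, "IOTA_EXPERT")
  expect_equal(rc$call, "high")
  expect_true(rc$fallback_used)
  expect_equal(rc$iota_call, "inconclusive")
  # inconclusive + RMI 450 (u=1, post, 3*150) -> high via RMI fallback
  rec <- make_record(menopausal = "post", ca125 = 150,
                     rmi_solid_areas = 1L)
  rc <- apply_strategy(rec, "IOTA_RMI")
  expect_equal(rc$rmi, 450)
  expect_equal(rc$call, "high")
  expect_true(rc$fallback_used)
})

test_that("missing components flag the record non-evaluable with a reason", {
  rec <- make_record(he4 = NA_real_)  # inconclusive, no HE4
  for (s in c("IOTA_ROMA", "ROMA_ALONE")) {
    rc <- apply_strategy(rec, s)
    expect_false(rc$evaluable)
    expect_equal(rc$reason, "he4 missing")
  }
  rec <- make_record()  # inconclusive, no expert call
  rc <- apply_strategy(rec, "IOTA_EXPERT")
  expect_false(rc$evaluable)
  expect_equal(rc$reason, "expert_call missing")
  rc <- apply_strategy(rec, "IOTA_ONLY")
  expect_false(rc$evaluable)
  expect_equal(rc$reason, "IOTA inconclusive")
  # zero markers make ROMA unavailable rather than an error
  rc <- apply_strategy(make_record(he4 = 0), "ROMA_ALONE")
  expect_false(rc$evaluable)
  expect_equal(rc$reason, "non-positive marker")
})

test_that("every record appears once per strategy, never silently dropped", {
  cohort <- generate_cohort(default_params(), n = 400, seed = 21)
  pred <- run_all_strategies(cohort)
  expect_equal(nrow(pred), 6 * nrow(cohort))
  counts <- table(pred$strategy)
  expect_true(all(counts == nrow(cohort)))
  expect_true(all(pred$evaluable | !is.na(pred$reason)))
})

test_that("strategy agreement invariants hold on generated cohorts", {
  cohort <- generate_cohort(default_params(), n = 2000, seed = 8)
  pred <- run_all_strategies(cohort)
  wide <- split(pred, pred$strategy)
  conclusive <- wide$IOTA_EXPERT$iota_call != "inconclusive"
  # the three IOTA-first strategies agree wherever the rules are conclusive
  expect_identical(wide$IOTA_EXPERT$call[conclusive],
                   wide$IOTA_ROMA$call[conclusive])
  expect_identical(wide$IOTA_ROMA$call[conclusive],
                   wide$IOTA_RMI$call[conclusive])
  # on inconclusive masses the combination equals the standalone score
  expect_identical(wide$IOTA_ROMA$call[!conclusive],
                   wide$ROMA_ALONE$call[!conclusive])
  expect_identical(wide$IOTA_RMI$call[!conclusive],
                   wide$RMI_ALONE$call[!conclusive])
  # fallback bookkeeping matches the inconclusive count exactly
  for (s in c("IOTA_EXPERT", "IOTA_ROMA", "IOTA_RMI"))
    expect_equal(sum(wide[[s]]$fallback_used & wide[[s]]$evaluable),
                 sum(!conclusive & wide[[s]]$evaluable))
  # determinism: identical inputs give identical prediction tables
  expect_identical(pred, run_all_strategies(cohort))
})
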