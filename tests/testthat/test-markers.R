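test_that("ROMA predictive index matches the published formulas", {
  # ln(1) = 0 leaves only the intercepts
  expect_equal(roma_pi(1, 1, "pre"), -12.0)
  expect_equal(roma_pi(1, 1, "post"), -8.09)
  # hand-evaluated: -12 + 2.38 ln(60) + 0.0626 ln(35)
  expect_equal(roma_pi(60, 35, "pre"), -2.032895, tolerance = 1e-6)
  expect_error(roma_pi(0, 35, "pre"), "non-positive")
  expect_error(roma_pi(50, -2, "post"), "non-positive")
  expect_true(is.na(roma_pi(NA, 35, "pre")))
})

test_that("ROMA score is the logistic transform on the percent scale", {
  expect_equal(roma_score(0), 50.0)
  expect_equal(roma_score(-2.033), 11.57814, tolerance = 1e-5)
  # extreme indices saturate without leaving (0, 100)
  expect_gte(roma_score(-800), 0)
  expect_lte(roma_score(800), 100)
  # against an independent high-precision evaluation of the whole chain
  set.seed(91)
  he4 <- exp(runif(1000, log(5), log(2000)))
  ca125 <- exp(runif(1000, log(1), log(5000)))
  meno <- sample(c("pre", "post"), 1000, replace = TRUE)
  got <- roma_score(roma_pi(he4, ca125, meno))
  a <- ifelse(meno == "pre", -12.0, -8.09)
  b <- ifelse(meno == "pre", 2.38, 1.04)
  cc <- ifelse(meno == "pre", 0.0626, 0.732)
  pi <- a + b * log(he4) + cc * log(ca125)
  oracle <- 100 * exp(pi) / (1 + exp(pi))
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("ROMA risk calls are inclusive at the menopause-specific cut-off", {
  thr <- triage_thresholds()
  expect_equal(classify_roma(7.4, "pre", thr), "high")
  expect_equal(classify_roma(25.29, "post", thr), "low")
  expect_equal(classify_roma(7.4, "post", thr), "low")
  expect_equal(classify_roma(25.3, "post", thr), "high")
})

test_that("ROMA score increases with either marker in both groups", {
  set.seed(14)
  for (meno in c("pre", "post")) {
    he4 <- exp(runif(200, log(10), log(500)))
    ca125 <- exp(runif(200, log(5), log(1000)))
    s0 <- roma_score(roma_pi(he4, ca125, meno))
    expect_true(all(roma_score(roma_pi(he4 * 1.3, ca125, meno)) > s0))
    expect_true(all(roma_score(roma_pi(he4, ca125 * 1.3, meno)) > s0))
  }
})

test_that("RMI ultrasound score maps feature counts to 0/1/3", {
  expect_equal(rmi_ultrasound_score(make_record()), 0L)
  expect_equal(rmi_ultrasound_score(make_record(rmi_ascites = 1L,
                                                m_ascites = 1L)), 1L)
  three <- make_record(rmi_multilocular = 1L, rmi_bilateral = 1L,
                       rmi_solid_areas = 1L)
  expect_equal(rmi_ultrasound_score(three), 3L)
  # missing feature flag makes the score unavailable, not zero
  expect_true(is.na(rmi_ultrasound_score(make_record(
    rmi_multilocular = NA_integer_))))
})

test_that("RMI is the U x M x CA125 product with an inclusive cut at 200", {
  thr <- triage_thresholds()
  r <- rmi_score(0L, "pre", 500, thr)
  expect_equal(r$rmi, 0)
  expect_equal(r$call, "low")
  r <- rmi_score(3L, "post", 50, thr)
  expect_equal(r$rmi, 450)
  expect_equal(r$call, "high")
  r <- rmi_score(1L, "pre", 150, thr)
  expect_equal(r$rmi, 150)
  expect_equal(r$call, "low")
  expect_equal(classify_rmi(200, thr), "high")
  expect_equal(classify_rmi(199.999, thr), "low")
  expect_equal(classify_rmi(0, thr), "low")
})

test_that("lowering a threshold can only move calls from low to high", {
  set.seed(3)
  score <- runif(500, 0, 100)
  strict <- classify_roma(score, "pre", triage_thresholds())
  lax <- classify_roma(score, "pre", triage_thresholds(roma_pre = 3))
  expect_true(all(lax[strict == "high"] == "high"))
  rmi <- runif(500, 0, 1000)
  strict <- classify_rmi(rmi, triage_thresholds())
  lax <- classify_rmi(rmi, triage_thresholds(rmi = 100))
  expect_true(all(lax[strict == "high"] == "high"))
})

test_that("thresholds must be strictly positive", {
  expect_error(triage_thresholds(roma_pre = 0), "positive")
  expect_error(triage_thresholds(rmi = -5), "positive")
})
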