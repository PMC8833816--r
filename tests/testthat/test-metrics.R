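test_that("confusion tables count prediction against histology", {
  cohort <- reference_cohort()
  pred <- run_all_strategies(cohort)
  inconclusive <- classify_iota(cohort)$call == "inconclusive"
  tab <- confusion_table(pred, cohort, "IOTA_EXPERT", subset = inconclusive)
  expect_equal(c(tab$tp, tab$fp, tab$fn, tab$tn), c(64, 26, 15, 66))
  tab <- confusion_table(pred, cohort, "ROMA_ALONE", subset = inconclusive)
  expect_equal(c(tab$tp, tab$fp, tab$fn, tab$tn), c(50, 25, 29, 67))
  # conservation: diseased margin equals histology count in the subset
  truth <- truth_malignant(cohort)
  expect_equal(tab$tp + tab$fn, sum(truth & inconclusive))
  expect_equal(tab$n, sum(inconclusive))
})

test_that("a perfect predictor yields an off-diagonal of zeros", {
  cohort <- generate_cohort(default_params(), n = 200, seed = 33)
  pred <- run_all_strategies(cohort)
  oracle <- pred[pred$strategy == "IOTA_ONLY", ]
  oracle$evaluable <- TRUE
  oracle$call <- ifelse(truth_malignant(cohort), "high", "low")
  tab <- confusion_table(oracle, cohort)
  expect_equal(tab$fp, 0)
  expect_equal(tab$fn, 0)
  expect_equal(tab$n, 200)
})

test_that("metric estimates follow their defining ratios", {
  m <- sens_spec_accuracy(new_two_by_two(64, 26, 15, 66))
  expect_equal(m$estimate[m$metric == "sensitivity"], 64 / 79)
  expect_equal(m$estimate[m$metric == "specificity"], 66 / 92)
  expect_equal(m$estimate[m$metric == "accuracy"], 130 / 171)
  m <- sens_spec_accuracy(new_two_by_two(1, 0, 0, 1))
  expect_equal(m$estimate, rep(1, 3))
  expect_equal(m$upper, rep(1, 3))
  # zero denominator flags the metric undefined instead of NaN
  m <- sens_spec_accuracy(new_two_by_two(0, 3, 0, 7))
  expect_true(is.na(m$estimate[m$metric == "sensitivity"]))
  expect_false(anyNA(m$estimate[m$metric != "sensitivity"]))
})

test_that("Clopper-Pearson intervals match the beta-quantile oracle", {
  ci <- proportion_ci(64, 79)
  expect_equal(ci$lower, 0.7062415, tolerance = 1e-6)
  expect_equal(ci$upper, 0.8896525, tolerance = 1e-6)
  expect_equal(proportion_ci(0, 10)$lower, 0)
  expect_equal(proportion_ci(10, 10)$upper, 1)
  # random spot checks against a direct beta-quantile evaluation
  set.seed(6)
  x <- rbinom(50, 100, 0.4)
  ci <- proportion_ci(x, 100)
  expect_equal(ci$lower, qbeta(0.025, x, 100 - x + 1), tolerance = 1e-12)
  expect_equal(ci$upper, qbeta(0.975, x + 1, 100 - x), tolerance = 1e-12)
})

test_that("Wilson intervals invert the score test", {
  ci <- proportion_ci(64, 79, method = "wilson")
  # every point inside the interval passes the score test at 5%
  z <- qnorm(0.975)
  score_ok <- function(p0, x, n)
    abs((x / n - p0) / sqrt(p0 * (1 - p0) / n)) <= z + 1e-9
  expect_true(score_ok(ci$lower + 1e-6, 64, 79))
  expect_true(score_ok(ci$upper - 1e-6, 64, 79))
  expect_false(score_ok(ci$lower - 1e-4, 64, 79))
  expect_false(score_ok(ci$upper + 1e-4, 64, 79))
})

test_that("exact McNemar p-values equal brute-force binomial enumeration", {
  p_oracle <- function(b, c) {
    n <- b + c
    if (n == 0) return(1)
    probs <- dbinom(0:n, n, 0.5)           # full enumeration
    min(1, 2 * sum(probs[0:n <= min(b, c)]))
  }
  for (b in 0:12) for (c in 0:(12 - b)) {
    got <- mcnemar_paired(c(rep(TRUE, b), rep(FALSE, c)),
                          c(rep(FALSE, b), rep(TRUE, c)))
    expect_equal(got$p_exact, p_oracle(b, c), tolerance = 1e-12)
  }
  # hand-derived tail: b=9, c=1 gives 2 * 11/1024
  got <- mcnemar_paired(c(rep(TRUE, 9), rep(FALSE, 1)),
                        c(rep(FALSE, 9), rep(TRUE, 1)))
  expect_equal(got$p_exact, 22 / 1024)
  expect_equal(mcnemar_paired(rep(TRUE, 4), rep(TRUE, 4))$p_exact, 1)
})

test_that("McNemar comparison is symmetric in its arguments", {
  set.seed(12)
  a <- runif(100) < 0.8
  b <- runif(100) < 0.7
  ab <- mcnemar_paired(a, b)
  ba <- mcnemar_paired(b, a)
  expect_equal(ab$p_exact, ba$p_exact)
  expect_equal(ab$p_cc, ba$p_cc)
  expect_equal(ab$b, ba$c)
})

test_that("strategy comparisons match hand enumeration on a tiny cohort", {
  # 8 records, all inconclusive: expert vs ROMA with known discordances
  recs <- list()
  truth <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expert <- c("malignant", "malignant", "benign", "malignant",
              "benign", "malignant", "benign", "benign")
  roma_hi <- c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE)
  for (i in 1:8)
    recs[[i]] <- make_record(
      patient_id = sprintf("H%d", i),
      histology = if (truth[i]) "malignant" else "benign",
      expert_call = expert[i],
      he4 = if (roma_hi[i]) 1000 else 10, ca125 = 40)
  cohort <- do.call(make_cohort, recs)
  pred <- run_all_strategies(cohort)
  cmp <- compare_strategies(cohort, pred, "IOTA_EXPERT", "ROMA_ALONE")
  # sensitivity stratum (records 1-4): expert correct 3, roma correct 1
  expect_equal(cmp$comparisons$sensitivity$b, 2)
  expect_equal(cmp$comparisons$sensitivity$c, 0)
  # specificity stratum (5-8): expert correct 3, roma correct 2
  expect_equal(cmp$comparisons$specificity$b, 1)
  expect_equal(cmp$comparisons$specificity$c, 0)
  expect_equal(cmp$n_analysed, 8)
  # a strategy against itself is all-concordant with p = 1
  self <- compare_strategies(cohort, pred, "ROMA_ALONE", "ROMA_ALONE")
  for (m in names(self$comparisons)) {
    expect_equal(self$comparisons[[m]]$b, 0)
    expect_equal(self$comparisons[[m]]$p_exact, 1)
  }
})

test_that("subgroup analysis partitions the cohort without loss", {
  cohort <- generate_cohort(default_params(), n = 1500, seed = 44)
  pred <- run_all_strategies(cohort)
  sub <- subgroup_analysis(cohort, pred, "iota_conclusiveness",
                           strategies = "ROMA_ALONE")
  acc <- sub[sub$metric == "accuracy", ]
  expect_setequal(acc$group, c("conclusive", "inconclusive"))
  expect_equal(sum(acc$denominator) + sum(acc$n_excluded), nrow(cohort))
  # stage grouping reports sensitivity only, as in stage-I tables
  stg <- subgroup_analysis(cohort, pred, "figo_stage")
  expect_true(all(stg$metric == "sensitivity"))
  # menopause grouping recovers the generator's per-group operating points
  men <- subgroup_analysis(cohort, pred, "menopause",
                           strategies = "IOTA_EXPERT")
  expect_setequal(men$group, c("premenopausal", "postmenopausal"))
})
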