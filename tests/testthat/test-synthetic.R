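test_that("default parameters are valid and imply the study's marginals", {
  params <- default_params()
  expect_silent(validate_generator_params(params))
  marg <- analytic_marginals(params)
  # site-mix weighted prevalence reproduces the overall ~21% malignancy
  expect_equal(unname(marg["prevalence"]),
               341 / 690 * 0.328 + 349 / 690 * 0.086, tolerance = 1e-12)
  # closed-form inconclusive rate lies in the reported one-in-four band
  expect_gt(marg["inconclusive_rate"], 0.20)
  expect_lt(marg["inconclusive_rate"], 0.30)
  # malignancy enriched among inconclusive masses (~31% in the study)
  expect_gt(marg["malignant_among_inconclusive"], marg["prevalence"])
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_cohort(default_params(), n = 300, seed = 17)
  b <- generate_cohort(default_params(), n = 300, seed = 17)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_cohort(default_params(), n = 300, seed = 18)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("generated cohorts satisfy every record-level invariant", {
  cohort <- generate_cohort(default_params(), n = 1000, seed = 2)
  expect_equal(nrow(validate_cohort(cohort)), 0)
  # flow flags derive from the colour score
  expect_identical(cohort$b_no_flow, as.integer(cohort$colour_score == 1))
  expect_identical(cohort$m_strong_flow,
                   as.integer(cohort$colour_score == 4))
  expect_identical(cohort$rmi_ascites, cohort$m_ascites)
  # expert assessment recorded exactly where the rules are inconclusive
  incl <- classify_iota(cohort)$call == "inconclusive"
  expect_identical(is.na(cohort$expert_call), !incl)
  # stages only on diseased records
  expect_identical(!is.na(cohort$figo_stage), truth_malignant(cohort))
})

test_that("empirical marginals track the configured values", {
  n <- 20000
  cohort <- generate_cohort(default_params(), n = n, seed = 9)
  marg <- analytic_marginals(default_params())
  tol <- function(p) 3 * sqrt(p * (1 - p) / n)
  prev <- mean(truth_malignant(cohort))
  expect_lt(abs(prev - marg["prevalence"]), tol(marg["prevalence"]))
  pre <- mean(cohort$menopausal == "pre")
  expect_lt(abs(pre - marg["premenopausal_frac"]),
            tol(marg["premenopausal_frac"]))
  incl <- mean(classify_iota(cohort)$call == "inconclusive")
  expect_lt(abs(incl - marg["inconclusive_rate"]),
            tol(marg["inconclusive_rate"]))
})

test_that("degenerate zero-scale markers give step-function ROMA points", {
  params <- default_params()
  for (cl in names(params$marker_dists)) {
    for (mk in c("ca125", "he4")) {
      params$marker_dists[[cl]][[mk]]$pre[2] <- 0
      params$marker_dists[[cl]][[mk]]$post[2] <- 0
    }
  }
  params$premenopausal_frac <- 1
  params$borderline_frac <- 0
  op <- analytic_operating_points(params)
  roma <- op[op$strategy == "ROMA_ALONE", ]
  expect_true(roma$sensitivity %in% c(0, 1))
  expect_true(roma$specificity %in% c(0, 1))
})

test_that("the expert stratum operates at its configured error rates", {
  # on inconclusive masses the expert call is a Bernoulli draw with the
  # configured sensitivity/specificity, by construction
  params <- default_params()
  op <- analytic_operating_points(params)
  n <- 30000
  cohort <- generate_cohort(params, n = n, seed = 13)
  incl <- classify_iota(cohort)$call == "inconclusive"
  truth <- truth_malignant(cohort)
  emp_sens <- mean(cohort$expert_call[incl & truth] == "malignant")
  emp_spec <- mean(cohort$expert_call[incl & !truth] == "benign")
  expect_lt(abs(emp_sens - params$expert_sens),
            3 * sqrt(0.81 * 0.19 / sum(incl & truth)))
  expect_lt(abs(emp_spec - params$expert_spec),
            3 * sqrt(0.717 * 0.283 / sum(incl & !truth)))
})

test_that("invalid generator parameters are rejected by name", {
  params <- default_params()
  params$prevalence <- 1.4
  expect_error(validate_generator_params(params), "prevalence")
  params <- default_params()
  params$feature_probs$benign$colour <- c(0.5, 0.5, 0.2, 0.2)
  expect_error(validate_generator_params(params), "colour")
  params <- default_params()
  params$marker_dists$benign$ca125$pre[2] <- -1
  expect_error(validate_generator_params(params), "ca125")
})
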