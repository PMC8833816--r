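#' Decision thresholds for the scoring systems
#'
#' Defaults are the published cut-offs: ROMA score >= 7.4 (premenopausal) or
#' >= 25.3 (postmenopausal) is high risk, RMI >= 200 is high risk.  All
#' comparisons are inclusive at the boundary.
#'
#' @param roma_pre premenopausal ROMA high-risk cut-off (percent scale).
#' @param roma_post postmenopausal ROMA high-risk cut-off (percent scale).
#' @param rmi RMI high-risk cut-off (units of CA125, U/mL).
#' @return a `triage_thresholds` list.
#' @export
triage_thresholds <- function(roma_pre = 7.4, roma_post = 25.3, rmi = 200) {
  for (v in c(roma_pre = roma_pre, roma_post = roma_post, rmi = rmi))
    if (!is.finite(v) || v <= 0)
      stopf("thresholds must be strictly positive")
  structure(list(roma_pre = roma_pre, roma_post = roma_post, rmi = rmi),
            class = "triage_thresholds")
}

ROMA_COEF <- list(pre  = c(intercept = -12.0, he4 = 2.38,  ca125 = 0.0626),
                  post = c(intercept = -8.09, he4 = 1.04,  ca125 = 0.732))

#' ROMA predictive index
#'
#' Menopause-specific linear predictor on the natural logs of the serum
#' markers: `-12.0 + 2.38 ln(HE4) + 0.0626 ln(CA125)` premenopausally and
#' `-8.09 + 1.04 ln(HE4) + 0.732 ln(CA125)` postmenopausally.
#'
#' Missing marker values propagate as `NA` (score unavailable); non-positive
#' values are a domain error, since the logarithm is undefined — callers that
#' prefer "unavailable" semantics for zero markers (as the triage strategies
#' do) must screen before calling.
#'
#' @param he4 serum HE4 in pmol/L, strictly positive.
#' @param ca125 serum CA125 in U/mL, strictly positive.
#' @param menopausal `"pre"` or `"post"` (recycled against the markers).
#' @return numeric vector of predictive-index values.
#' @export
roma_pi <- function(he4, ca125, menopausal) {
  n <- max(length(he4), length(ca125), length(menopausal))
  he4 <- rep_len(he4, n); ca125 <- rep_len(ca125, n)
  menopausal <- rep_len(menopausal, n)
  if (!all(menopausal %in% c("pre", "post")))
    stopf("menopausal must be 'pre' or 'post'")
  if (any(!is.na(he4) & he4 <= 0) || any(!is.na(ca125) & ca125 <= 0))
    stopf("ROMA is undefined for non-positive marker values (log domain)")
  cf <- do.call(rbind, ROMA_COEF[menopausal])
  unname(cf[, "intercept"] + cf[, "he4"] * log(he4) +
           cf[, "ca125"] * log(ca125))
}

#' ROMA score
#'
#' Logistic transform of the predictive index on a 0-100 percent scale:
#' `100 exp(PI) / (1 + exp(PI))`.  Computed via [stats::plogis()] so very
#' negative indices underflow to 0 (never below) and very positive ones
#' saturate at 100.
#'
#' @param pi predictive index from [roma_pi()].
#' @return numeric vector in (0, 100).
#' @export
roma_score <- function(pi) 100 * stats::plogis(pi)

#' Classify a ROMA score as high or low risk
#'
#' @param score ROMA score (percent scale).
#' @param menopausal `"pre"` or `"post"`.
#' @param thresholds a [triage_thresholds()] object.
#' @return character vector, `"high"` or `"low"` (`NA` score gives `NA`).
#' @export
classify_roma <- function(score, menopausal, thresholds = triage_thresholds()) {
  cut <- ifelse(menopausal == "pre", thresholds$roma_pre,
                thresholds$roma_post)
  ifelse(is.na(score), NA_character_, ifelse(score >= cut, "high", "low"))
}

#' RMI ultrasound score
#'
#' Scores the five RMI ultrasound features (multilocular cyst, solid areas,
#' metastases, ascites, bilateral lesions): 0 for no feature, 1 for exactly
#' one, 3 for two or more.  Any missing feature flag makes the score `NA`.
#'
#' @param exam data frame carrying the five `rmi_*` flags.
#' @return integer vector with values 0, 1, 3 or `NA`.
#' @export
rmi_ultrasound_score <- function(exam) {
  k <- rowSums(as.data.frame(exam)[RMI_FEATURES])
  as.integer(ifelse(is.na(k), NA, ifelse(k == 0, 0, ifelse(k == 1, 1, 3))))
}

#' Risk of Malignancy Index
#'
#' `RMI = U x M x CA125` with the ultrasound score U in \{0, 1, 3\} and the
#' menopausal score M = 1 (pre) or 3 (post); high risk when RMI >= 200.
#'
#' @param u ultrasound score from [rmi_ultrasound_score()].
#' @param menopausal `"pre"` or `"post"`.
#' @param ca125 serum CA125 in U/mL, non-negative.
#' @param thresholds a [triage_thresholds()] object.
#' @return data frame with columns `u`, `m`, `rmi`, `call`.
#' @export
rmi_score <- function(u, menopausal, ca125,
                      thresholds = triage_thresholds()) {
  if (any(!is.na(ca125) & ca125 < 0)) stopf("ca125 must be >= 0")
  m <- ifelse(menopausal == "pre", 1L, 3L)
  rmi <- u * m * ca125
  data.frame(u = u, m = m, rmi = rmi,
             call = classify_rmi(rmi, thresholds))
}

#' Classify an RMI value as high or low risk
#'
#' @param rmi RMI value (units of CA125).
#' @param thresholds a [triage_thresholds()] object.
#' @return character vector, `"high"` or `"low"` (`NA` in gives `NA` out).
#' @export
classify_rmi <- function(rmi, thresholds = triage_thresholds()) {
  ifelse(is.na(rmi), NA_character_,
         ifelse(rmi >= thresholds$rmi, "high", "low"))
}
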