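#' Count IOTA benign and malignant features
#'
#' @param exam data frame (e.g. a `triage_cohort`) carrying the five
#'   B-feature and five M-feature flags.
#' @return data frame with integer columns `n_b`, `n_m` (0-5 each).
#' @export
count_features <- function(exam) {
  data.frame(
    n_b = as.integer(rowSums(as.data.frame(exam)[B_FEATURES])),
    n_m = as.integer(rowSums(as.data.frame(exam)[M_FEATURES])))
}

#' IOTA simple-rules three-way classification
#'
#' A mass is called malignant when one or more M-features are present in the
#' absence of any B-feature, benign when one or more B-features are present
#' in the absence of any M-feature, and inconclusive otherwise (no features
#' at all, or features of both kinds).
#'
#' @inheritParams count_features
#' @return data frame with columns `n_b`, `n_m` and `call` (one of
#'   `"benign"`, `"malignant"`, `"inconclusive"`).
#' @export
classify_iota <- function(exam) {
  counts <- count_features(exam)
  call <- rep("inconclusive", nrow(counts))
  call[counts$n_m >= 1 & counts$n_b == 0] <- "malignant"
  call[counts$n_b >= 1 & counts$n_m == 0] <- "benign"
  counts$call <- call
  counts
}
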