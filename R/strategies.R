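#' Triage strategy names
#'
#' The five prediction strategies compared by the pipeline, plus
#' `"IOTA_ONLY"`, a pseudo-strategy defined only on records with a
#' conclusive simple-rules result (used to reproduce the conclusive-subset
#' analyses directly):
#'
#' * `IOTA_EXPERT` — IOTA simple rules; inconclusive masses take the expert
#'   ultrasound call.
#' * `IOTA_ROMA` — IOTA simple rules; inconclusive masses take the ROMA call.
#' * `IOTA_RMI` — IOTA simple rules; inconclusive masses take the RMI call.
#' * `ROMA_ALONE`, `RMI_ALONE` — the marker scores ignoring IOTA.
#' * `IOTA_ONLY` — simple rules on the conclusive subset.
#'
#' @return character vector of strategy names.
#' @export
triage_strategies <- function() {
  c("IOTA_EXPERT", "IOTA_ROMA", "IOTA_RMI", "ROMA_ALONE", "RMI_ALONE",
    "IOTA_ONLY")
}

# per-record component calls shared by all strategies
component_calls <- function(cohort, thresholds) {
  iota <- classify_iota(cohort)

  roma_ok <- !is.na(cohort$he4) & cohort$he4 > 0 &
    !is.na(cohort$ca125) & cohort$ca125 > 0
  score <- rep(NA_real_, nrow(cohort))
  if (any(roma_ok))
    score[roma_ok] <- roma_score(roma_pi(cohort$he4[roma_ok],
                                         cohort$ca125[roma_ok],
                                         cohort$menopausal[roma_ok]))
  roma_call <- classify_roma(score, cohort$menopausal, thresholds)
  roma_reason <- ifelse(roma_ok, NA_character_,
                        ifelse(is.na(cohort$he4), "he4 missing",
                               ifelse(cohort$he4 == 0 | cohort$ca125 == 0,
                                      "non-positive marker",
                                      "ca125 missing")))

  u <- rmi_ultrasound_score(cohort)
  rmi <- rmi_score(u, cohort$menopausal, cohort$ca125, thresholds)
  rmi_reason <- ifelse(!is.na(rmi$call), NA_character_, "rmi features missing")

  list(iota = iota, roma_score = score, roma_call = roma_call,
       roma_reason = roma_reason, rmi = rmi, rmi_reason = rmi_reason)
}

#' Run every triage strategy over a cohort
#'
#' Produces one row per record x strategy.  IOTA-first strategies call high
#' risk when the simple rules say malignant, low risk when they say benign,
#' and otherwise delegate to their fallback (expert call, ROMA or RMI).  A
#' record missing the component a strategy needs is flagged non-evaluable
#' with a reason — never silently dropped.
#'
#' @param cohort a `triage_cohort`.
#' @param thresholds a [triage_thresholds()] object.
#' @return data frame of class `triage_predictions` with columns
#'   `patient_id`, `strategy`, `evaluable`, `reason`, `call`, `iota_call`,
#'   `fallback_used`, `roma_score`, `rmi`, `expert_call`.
#' @export
run_all_strategies <- function(cohort, thresholds = triage_thresholds()) {
  comp <- component_calls(cohort, thresholds)
  iota_call <- comp$iota$call
  conclusive <- iota_call != "inconclusive"
  iota_high <- ifelse(conclusive,
                      ifelse(iota_call == "malignant", "high", "low"),
                      NA_character_)
  expert_high <- ifelse(is.na(cohort$expert_call), NA_character_,
                        ifelse(cohort$expert_call == "malignant",
                               "high", "low"))

  iota_first <- function(strategy, fb_call, fb_reason) {
    call <- ifelse(conclusive, iota_high, fb_call)
    reason <- ifelse(conclusive, NA_character_, fb_reason)
    data.frame(patient_id = cohort$patient_id, strategy = strategy,
               evaluable = !is.na(call),
               reason = ifelse(is.na(call), reason, NA_character_),
               call = call, iota_call = iota_call,
               fallback_used = !conclusive & !is.na(call),
               roma_score = comp$roma_score, rmi = comp$rmi$rmi,
               expert_call = cohort$expert_call,
               stringsAsFactors = FALSE)
  }
  standalone <- function(strategy, call, reason) {
    data.frame(patient_id = cohort$patient_id, strategy = strategy,
               evaluable = !is.na(call),
               reason = ifelse(is.na(call), reason, NA_character_),
               call = call, iota_call = iota_call, fallback_used = FALSE,
               roma_score = comp$roma_score, rmi = comp$rmi$rmi,
               expert_call = cohort$expert_call,
               stringsAsFactors = FALSE)
  }

  pred <- rbind(
    iota_first("IOTA_EXPERT", expert_high,
               ifelse(is.na(expert_high), "expert_call missing",
                      NA_character_)),
    iota_first("IOTA_ROMA", comp$roma_call, comp$roma_reason),
    iota_first("IOTA_RMI", comp$rmi$call, comp$rmi_reason),
    standalone("ROMA_ALONE", comp$roma_call, comp$roma_reason),
    standalone("RMI_ALONE", comp$rmi$call, comp$rmi_reason),
    standalone("IOTA_ONLY", iota_high,
               ifelse(conclusive, NA_character_, "IOTA inconclusive")))
  rownames(pred) <- NULL
  class(pred) <- c("triage_predictions", "data.frame")
  pred
}

#' Apply one strategy to one record
#'
#' Single-record convenience wrapper around [run_all_strategies()].
#'
#' @param record one-row data frame with the cohort columns.
#' @param strategy one of [triage_strategies()].
#' @param thresholds a [triage_thresholds()] object.
#' @return one-row data frame (a risk call) as in [run_all_strategies()].
#' @export
apply_strategy <- function(record, strategy,
                           thresholds = triage_thresholds()) {
  strategy <- match.arg(strategy, triage_strategies())
  record <- as.data.frame(record, stringsAsFactors = FALSE)
  pred <- run_all_strategies(record, thresholds)
  out <- pred[pred$strategy == strategy, , drop = FALSE]
  rownames(out) <- NULL
  out
}
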