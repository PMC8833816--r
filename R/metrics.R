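#' Two-by-two diagnostic table
#'
#' Cross-tabulates a strategy's high/low risk calls against the histology
#' reference standard (borderline counted as malignant).
#'
#' @param predictions a `triage_predictions` table from
#'   [run_all_strategies()] (or any data frame with `patient_id`,
#'   `strategy`, `evaluable`, `call`).
#' @param cohort the `triage_cohort` the predictions were made on.
#' @param strategy which strategy to tabulate (may be omitted when
#'   `predictions` holds a single strategy).
#' @param subset optional logical vector along the cohort rows restricting
#'   the analysed population (e.g. `cohort$ovarian == 1`).
#' @return object of class `two_by_two`: list with counts `tp`, `fp`, `fn`,
#'   `tn`, the analysed size `n`, the strategy, and `n_excluded`
#'   (non-evaluable records inside the subset).
#' @export
confusion_table <- function(predictions, cohort, strategy = NULL,
                            subset = NULL) {
  if (is.null(strategy)) {
    strategy <- unique(predictions$strategy)
    if (length(strategy) != 1)
      stopf("predictions contain %d strategies; pass `strategy`",
            length(strategy))
  }
  pred <- predictions[predictions$strategy == strategy, , drop = FALSE]
  miss <- setdiff(pred$patient_id, cohort$patient_id)
  if (length(miss) > 0)
    stopf("predictions without a matching cohort record: %s",
          paste(utils::head(miss, 3), collapse = ", "))
  idx <- match(pred$patient_id, cohort$patient_id)
  keep <- if (is.null(subset)) rep(TRUE, length(idx)) else subset[idx]
  pred <- pred[keep, , drop = FALSE]
  idx <- idx[keep]
  n_excluded <- sum(!pred$evaluable)
  use <- pred$evaluable
  truth <- truth_malignant(cohort)[idx[use]]
  high <- pred$call[use] == "high"
  new_two_by_two(tp = sum(high & truth), fp = sum(high & !truth),
                 fn = sum(!high & truth), tn = sum(!high & !truth),
                 strategy = strategy, n_excluded = n_excluded)
}

#' Construct a two-by-two table from counts
#'
#' @param tp,fp,fn,tn non-negative counts: prediction high/low crossed with
#'   histology malignant/benign.
#' @param strategy optional label.
#' @param n_excluded optional count of non-evaluable records.
#' @return a `two_by_two` object.
#' @export
new_two_by_two <- function(tp, fp, fn, tn, strategy = NA_character_,
                           n_excluded = 0L) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stopf("tp, fp, fn, tn must be non-negative integers")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 n = as.integer(tp + fp + fn + tn),
                 strategy = strategy, n_excluded = as.integer(n_excluded)),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  cat(sprintf("2x2 table%s (n = %d analysed%s)\n",
              if (is.na(x$strategy)) "" else paste0(" for ", x$strategy),
              x$n,
              if (x$n_excluded > 0)
                sprintf(", %d non-evaluable excluded", x$n_excluded)
              else ""))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("high risk", "low risk"),
                              c("malignant", "benign")))
  print(m)
  invisible(x)
}

#' Binomial proportion confidence interval
#'
#' Clopper-Pearson (exact, via beta quantiles) or Wilson (score inversion).
#' Boundaries are exact: the lower bound is 0 when `x = 0` and the upper
#' bound is 1 when `x = n`.
#'
#' @param x successes (vectorised).
#' @param n trials, `n >= 1`.
#' @param method `"clopper_pearson"` (default) or `"wilson"`.
#' @param level confidence level, default 0.95.
#' @return data frame with columns `lower`, `upper`.
#' @export
proportion_ci <- function(x, n, method = c("clopper_pearson", "wilson"),
                          level = 0.95) {
  method <- match.arg(method)
  if (any(n < 1) || any(x < 0) || any(x > n))
    stopf("need 0 <= x <= n and n >= 1")
  k <- max(length(x), length(n))
  x <- rep_len(x, k); n <- rep_len(n, k)
  alpha <- 1 - level
  if (method == "clopper_pearson") {
    lower <- ifelse(x == 0, 0, stats::qbeta(alpha / 2, x, n - x + 1))
    upper <- ifelse(x == n, 1, stats::qbeta(1 - alpha / 2, x + 1, n - x))
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    p <- x / n
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lower <- pmax(0, centre - half)
    upper <- pmin(1, centre + half)
  }
  data.frame(lower = lower, upper = upper)
}

#' Sensitivity, specificity and accuracy with confidence intervals
#'
#' Sensitivity is `tp / (tp + fn)`, specificity `tn / (tn + fp)`, accuracy
#' (correct assessments over all assessments) `(tp + tn) / n`.  A metric
#' with a zero denominator is flagged undefined (`NA` estimate) rather than
#' propagating NaN.
#'
#' @param table a `two_by_two` object (or list with `tp`, `fp`, `fn`, `tn`).
#' @param method CI method, see [proportion_ci()].
#' @param level confidence level.
#' @return data frame of class `diag_metrics` with one row per metric and
#'   columns `metric`, `numerator`, `denominator`, `estimate`, `lower`,
#'   `upper`, `method`, `level`.
#' @export
sens_spec_accuracy <- function(table, method = c("clopper_pearson", "wilson"),
                               level = 0.95) {
  method <- match.arg(method)
  num <- c(sensitivity = table$tp,
           specificity = table$tn,
           accuracy = table$tp + table$tn)
  den <- c(sensitivity = table$tp + table$fn,
           specificity = table$tn + table$fp,
           accuracy = table$tp + table$fp + table$fn + table$tn)
  est <- ifelse(den > 0, num / den, NA_real_)
  lower <- upper <- rep(NA_real_, 3)
  ok <- den > 0
  if (any(ok)) {
    ci <- proportion_ci(num[ok], den[ok], method, level)
    lower[ok] <- ci$lower
    upper[ok] <- ci$upper
  }
  out <- data.frame(metric = names(num), numerator = as.integer(num),
                    denominator = as.integer(den), estimate = est,
                    lower = lower, upper = upper, method = method,
                    level = level, stringsAsFactors = FALSE)
  if (!is.null(table$strategy) && !is.na(table$strategy))
    out$strategy <- table$strategy
  rownames(out) <- NULL
  class(out) <- c("diag_metrics", "data.frame")
  out
}

#' @export
print.diag_metrics <- function(x, ...) {
  df <- as.data.frame(x)
  df$formatted <- ifelse(is.na(df$estimate), "undefined",
                         fmt_est_ci(df$numerator, df$denominator,
                                    df$lower, df$upper))
  print(df[c("metric", "numerator", "denominator", "formatted")],
        row.names = FALSE)
  invisible(x)
}

#' Paired McNemar comparison of two correctness vectors
#'
#' Compares two classifiers evaluated on the same records through the
#' discordant pairs: `b` records correct by A only, `c` correct by B only.
#' Reports the exact two-sided binomial p-value (doubled smaller tail of
#' Bin(b + c, 1/2), capped at 1) and the continuity-corrected chi-square
#' p-value `(|b - c| - 1)^2 / (b + c)` on 1 df.  With no discordant pairs
#' both p-values are 1 by convention.
#'
#' @param correct_a,correct_b logical vectors of equal length, aligned on
#'   the same records: was each record classified correctly?
#' @param metric,subset optional labels carried into the result.
#' @return object of class `paired_comparison`: list with `b`, `c`,
#'   `n_pairs`, `statistic`, `p_exact`, `p_cc`, `metric`, `subset`.
#' @export
mcnemar_paired <- function(correct_a, correct_b, metric = NA_character_,
                           subset = NA_character_) {
  if (length(correct_a) != length(correct_b))
    stopf("correctness vectors differ in length (%d vs %d)",
          length(correct_a), length(correct_b))
  if (anyNA(correct_a) || anyNA(correct_b))
    stopf("correctness vectors must not contain NA")
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  d <- b + cc
  if (d == 0) {
    statistic <- 0
    p_exact <- p_cc <- 1
  } else {
    statistic <- (abs(b - cc) - 1)^2 / d
    p_cc <- stats::pchisq(statistic, df = 1, lower.tail = FALSE)
    p_exact <- min(1, 2 * stats::pbinom(min(b, cc), d, 0.5))
  }
  structure(list(b = b, c = cc, n_pairs = length(correct_a),
                 statistic = statistic, p_exact = p_exact, p_cc = p_cc,
                 metric = metric, subset = subset),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("McNemar paired comparison%s\n",
              if (is.na(x$metric)) "" else paste0(" (", x$metric, ")")))
  cat(sprintf("  discordant pairs: b = %d, c = %d of %d\n",
              x$b, x$c, x$n_pairs))
  cat(sprintf("  exact p = %.4g, continuity-corrected p = %.4g\n",
              x$p_exact, x$p_cc))
  invisible(x)
}

# per-record correctness of one strategy on the evaluable subset
correctness_flags <- function(predictions, cohort, strategy) {
  pred <- predictions[predictions$strategy == strategy, , drop = FALSE]
  idx <- match(pred$patient_id, cohort$patient_id)
  if (anyNA(idx)) stopf("predictions without a matching cohort record")
  truth <- truth_malignant(cohort)[idx]
  correct <- ifelse(pred$evaluable,
                    (pred$call == "high") == truth, NA)
  data.frame(patient_id = pred$patient_id, row = idx, truth = truth,
             evaluable = pred$evaluable, correct = correct,
             stringsAsFactors = FALSE)
}

#' Paired comparison of two triage strategies
#'
#' Compares two strategies on the intersection of their evaluable records
#' (within an optional subset), giving McNemar comparisons for sensitivity
#' (histology-malignant records), specificity (histology-benign records) and
#' accuracy (all analysed records), plus both strategies' metric estimates
#' on that common population.
#'
#' @param cohort a `triage_cohort`.
#' @param predictions output of [run_all_strategies()].
#' @param strategy_a,strategy_b strategies to compare.
#' @param subset optional logical vector along the cohort rows.
#' @param method,level CI method and level for the metric estimates.
#' @return object of class `strategy_comparison`: list with the three
#'   `paired_comparison`s (`comparisons`), both strategies' `diag_metrics`
#'   (`metrics_a`, `metrics_b`), `n_analysed` and the per-strategy counts of
#'   records excluded as non-evaluable.
#' @export
compare_strategies <- function(cohort, predictions, strategy_a, strategy_b,
                               subset = NULL,
                               method = c("clopper_pearson", "wilson"),
                               level = 0.95) {
  method <- match.arg(method)
  fa <- correctness_flags(predictions, cohort, strategy_a)
  fb <- correctness_flags(predictions, cohort, strategy_b)
  fb <- fb[match(fa$patient_id, fb$patient_id), , drop = FALSE]
  keep <- if (is.null(subset)) rep(TRUE, nrow(fa)) else subset[fa$row]
  both <- keep & fa$evaluable & fb$evaluable
  if (!any(both)) {
    empty <- stats::setNames(
      rep(list(NULL), 3), c("sensitivity", "specificity", "accuracy"))
    return(structure(list(strategy_a = strategy_a, strategy_b = strategy_b,
                          comparisons = empty, metrics_a = NULL,
                          metrics_b = NULL, n_analysed = 0L,
                          n_excluded_a = sum(keep & !fa$evaluable),
                          n_excluded_b = sum(keep & !fb$evaluable)),
                     class = "strategy_comparison"))
  }
  fa2 <- fa[both, ]; fb2 <- fb[both, ]
  strata <- list(sensitivity = fa2$truth,
                 specificity = !fa2$truth,
                 accuracy = rep(TRUE, nrow(fa2)))
  comparisons <- lapply(names(strata), function(m) {
    s <- strata[[m]]
    mcnemar_paired(fa2$correct[s], fb2$correct[s], metric = m)
  })
  names(comparisons) <- names(strata)

  common <- rep(FALSE, nrow(cohort)); common[fa$row[both]] <- TRUE
  metrics_a <- sens_spec_accuracy(
    confusion_table(predictions, cohort, strategy_a, subset = common),
    method, level)
  metrics_b <- sens_spec_accuracy(
    confusion_table(predictions, cohort, strategy_b, subset = common),
    method, level)
  structure(list(strategy_a = strategy_a, strategy_b = strategy_b,
                 comparisons = comparisons, metrics_a = metrics_a,
                 metrics_b = metrics_b, n_analysed = nrow(fa2),
                 n_excluded_a = sum(keep & !fa$evaluable),
                 n_excluded_b = sum(keep & !fb$evaluable)),
            class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat(sprintf("Paired comparison: %s vs %s (n = %d common evaluable)\n",
              x$strategy_a, x$strategy_b, x$n_analysed))
  for (m in names(x$comparisons)) {
    cmp <- x$comparisons[[m]]
    if (is.null(cmp)) next
    ea <- x$metrics_a$estimate[x$metrics_a$metric == m]
    eb <- x$metrics_b$estimate[x$metrics_b$metric == m]
    cat(sprintf("  %-11s %s vs %s, exact p = %.4g (b = %d, c = %d)\n", m,
                ifelse(is.na(ea), "undef", fmt_pct(100 * ea)),
                ifelse(is.na(eb), "undef", fmt_pct(100 * eb)),
                cmp$p_exact, cmp$b, cmp$c))
  }
  invisible(x)
}

#' Subgroup diagnostic performance
#'
#' Splits the cohort by a grouping variable and computes each strategy's
#' metrics per group.  Groupings that slice within the diseased population
#' (`figo_stage`, `histology_class`) report sensitivity only, mirroring the
#' usual stage-I and histotype sensitivity tables; the others report all
#' three metrics.  Empty groups are omitted and listed in the `"log"`
#' attribute.
#'
#' @param cohort a `triage_cohort`.
#' @param predictions output of [run_all_strategies()].
#' @param grouping one of `"menopause"`, `"site"`, `"figo_stage"`,
#'   `"histology_class"`, `"iota_conclusiveness"`.
#' @param strategies strategies to include (default all).
#' @param method,level CI method and level.
#' @return data frame of class `subgroup_metrics`: columns `grouping`,
#'   `group`, `strategy`, plus the [sens_spec_accuracy()] columns.
#' @export
subgroup_analysis <- function(cohort, predictions,
                              grouping = c("menopause", "site", "figo_stage",
                                           "histology_class",
                                           "iota_conclusiveness"),
                              strategies = triage_strategies(),
                              method = c("clopper_pearson", "wilson"),
                              level = 0.95) {
  grouping <- match.arg(grouping)
  method <- match.arg(method)
  truth <- truth_malignant(cohort)
  group <- switch(grouping,
    menopause = ifelse(cohort$menopausal == "pre",
                       "premenopausal", "postmenopausal"),
    site = cohort$site,
    figo_stage = ifelse(truth, cohort$figo_stage, NA_character_),
    histology_class = ifelse(truth, cohort$histology, NA_character_),
    iota_conclusiveness = ifelse(classify_iota(cohort)$call == "inconclusive",
                                 "inconclusive", "conclusive"))
  sens_only <- grouping %in% c("figo_stage", "histology_class")
  levels <- sort(unique(group[!is.na(group)]))
  log <- character()
  rows <- list()
  for (lev in levels) {
    in_group <- !is.na(group) & group == lev
    if (!any(in_group)) { log <- c(log, sprintf("group %s empty", lev)); next }
    for (s in strategies) {
      tab <- confusion_table(predictions, cohort, s, subset = in_group)
      if (tab$n == 0) {
        log <- c(log, sprintf("group %s: no evaluable records for %s",
                              lev, s))
        next
      }
      m <- sens_spec_accuracy(tab, method, level)
      if (sens_only) m <- m[m$metric == "sensitivity", , drop = FALSE]
      m$grouping <- grouping
      m$group <- lev
      m$strategy <- s
      m$n_excluded <- tab$n_excluded
      rows[[length(rows) + 1]] <- m
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(metric = character(), numerator = integer(),
               denominator = integer(), estimate = numeric(),
               lower = numeric(), upper = numeric(), method = character(),
               level = numeric(), strategy = character(),
               grouping = character(), group = character(),
               n_excluded = integer(), stringsAsFactors = FALSE)
  out <- out[c("grouping", "group", "strategy", "metric", "numerator",
               "denominator", "estimate", "lower", "upper", "method",
               "level", "n_excluded")]
  rownames(out) <- NULL
  attr(out, "log") <- log
  class(out) <- c("subgroup_metrics", "data.frame")
  out
}
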