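#' Full triage analysis of a cohort
#'
#' The main entry point: runs every triage strategy over the cohort,
#' tabulates each against the histology reference standard (borderline
#' counted as malignant) and computes sensitivity, specificity and accuracy
#' with confidence intervals, overall and for any requested subgroups.
#' Returns a classed object with `print`, `summary` and `as.data.frame`
#' methods.
#'
#' @param cohort a `triage_cohort`.
#' @param thresholds a [triage_thresholds()] object.
#' @param method CI method, see [proportion_ci()].
#' @param level confidence level.
#' @param subgroups character vector of groupings for [subgroup_analysis()]
#'   (default none).
#' @param subset optional logical vector restricting the analysed
#'   population (e.g. `cohort$ovarian == 1` for the ovarian-pathology
#'   analysis); subgroups are computed within it.
#' @return object of class `triage_analysis`: list with `cohort_size`,
#'   `n_analysed`, `prevalence`, the long `metrics` table, per-strategy
#'   `evaluable` counts and exclusion `reasons`, the `predictions` table,
#'   and any `subgroups`.
#' @export
triage_analysis <- function(cohort, thresholds = triage_thresholds(),
                            method = c("clopper_pearson", "wilson"),
                            level = 0.95, subgroups = character(),
                            subset = NULL) {
  method <- match.arg(method)
  stopifnot(is.data.frame(cohort))
  predictions <- run_all_strategies(cohort, thresholds)
  keep <- if (is.null(subset)) rep(TRUE, nrow(cohort)) else subset

  metrics <- list()
  evaluable <- integer()
  reasons <- list()
  for (s in triage_strategies()) {
    tab <- confusion_table(predictions, cohort, s, subset = keep)
    m <- sens_spec_accuracy(tab, method, level)
    m$strategy <- s
    m$n_excluded <- tab$n_excluded
    metrics[[s]] <- m
    evaluable[s] <- tab$n
    pr <- predictions[predictions$strategy == s, ]
    pr <- pr[keep[match(pr$patient_id, cohort$patient_id)], ]
    reasons[[s]] <- table(pr$reason[!pr$evaluable])
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL

  sub <- lapply(stats::setNames(subgroups, subgroups), function(g) {
    subgroup_analysis(cohort[keep, , drop = FALSE],
                      predictions[keep[match(predictions$patient_id,
                                             cohort$patient_id)], ,
                                  drop = FALSE],
                      grouping = g, method = method, level = level)
  })

  truth <- truth_malignant(cohort)[keep]
  structure(list(cohort_size = nrow(cohort), n_analysed = sum(keep),
                 prevalence = mean(truth),
                 thresholds = thresholds, method = method, level = level,
                 metrics = metrics, evaluable = evaluable,
                 reasons = reasons, predictions = predictions,
                 subgroups = sub),
            class = "triage_analysis")
}

#' @export
print.triage_analysis <- function(x, ...) {
  cat(sprintf(
    "Pelvic-mass triage analysis: %d records analysed (of %d), %.1f%% malignant\n",
    x$n_analysed, x$cohort_size, 100 * x$prevalence))
  cat(sprintf("CI method: %s, level %.0f%%\n\n", x$method, 100 * x$level))
  wide <- do.call(rbind, lapply(split(x$metrics, x$metrics$strategy),
                                function(m) {
    data.frame(strategy = m$strategy[1],
               n = m$denominator[m$metric == "accuracy"],
               sensitivity = fmt_one(m, "sensitivity"),
               specificity = fmt_one(m, "specificity"),
               accuracy = fmt_one(m, "accuracy"),
               stringsAsFactors = FALSE)
  }))
  wide <- wide[match(triage_strategies(), wide$strategy), ]
  print(wide, row.names = FALSE)
  if (length(x$subgroups) > 0)
    cat(sprintf("\nSubgroup tables: %s (see summary())\n",
                paste(names(x$subgroups), collapse = ", ")))
  invisible(x)
}

fmt_one <- function(m, metric) {
  r <- m[m$metric == metric, ]
  if (nrow(r) == 0 || is.na(r$estimate)) return("undefined")
  fmt_est_ci(r$numerator, r$denominator, r$lower, r$upper)
}

#' @export
summary.triage_analysis <- function(object, ...) {
  structure(list(analysis = object), class = "summary.triage_analysis")
}

#' @export
print.summary.triage_analysis <- function(x, ...) {
  a <- x$analysis
  print(a)
  for (s in names(a$reasons)) {
    r <- a$reasons[[s]]
    if (length(r) > 0 && sum(r) > 0)
      cat(sprintf("Non-evaluable for %s: %s\n", s,
                  paste(sprintf("%s (%d)", names(r), r), collapse = ", ")))
  }
  for (g in names(a$subgroups)) {
    cat(sprintf("\n-- subgroup: %s --\n", g))
    print(render_table(a$subgroups[[g]], style = "text"))
  }
  invisible(x)
}

#' @export
as.data.frame.triage_analysis <- function(x, ...) {
  as.data.frame(x$metrics)
}
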