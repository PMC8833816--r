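#' Pipeline configuration
#'
#' Exactly one of `input` (a cohort CSV) or `params` (generator parameters)
#' must be supplied.
#'
#' @param input path to a cohort CSV, or `NULL`.
#' @param params a `generator_params` list, or `NULL`.
#' @param out_dir output directory (created if absent).
#' @param thresholds a [triage_thresholds()] object.
#' @param method CI method.
#' @param level confidence level.
#' @param subgroups subgroup analyses to run.
#' @param subset_ovarian restrict the analysis to ovarian masses
#'   (`ovarian == 1`), as in the whole-population tables of the study
#'   design this mirrors.
#' @param seed RNG seed for generation.
#' @param strict validation mode for [read_cohort()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, params = NULL, out_dir = "triage-report",
                            thresholds = triage_thresholds(),
                            method = c("clopper_pearson", "wilson"),
                            level = 0.95,
                            subgroups = c("menopause", "site", "figo_stage",
                                          "histology_class",
                                          "iota_conclusiveness"),
                            subset_ovarian = FALSE, seed = NULL,
                            strict = TRUE) {
  if (is.null(input) == is.null(params))
    stopf("exactly one of `input` or `params` must be given")
  method <- match.arg(method)
  structure(list(input = input, params = params, out_dir = out_dir,
                 thresholds = thresholds, method = method, level = level,
                 subgroups = subgroups, subset_ovarian = subset_ovarian,
                 seed = seed, strict = strict),
            class = "pipeline_config")
}

#' Run the full triage pipeline
#'
#' Reads (or generates) a cohort, runs [triage_analysis()], and writes the
#' report bundle to the output directory: `overall_metrics.csv` /
#' `overall_metrics.txt` (per-strategy metrics, text formatted as
#' `"81.0% (70.3–88.6%)"`), one `subgroup_<grouping>.csv` per requested
#' subgroup, `predictions.csv` (per record x strategy calls with
#' evaluability and reasons), and `manifest.json` (seed, configuration
#' digest, record accounting and per-strategy evaluable counts).
#'
#' @param config a [pipeline_config()].
#' @return the report bundle (list with `cohort`, `analysis`, `files`),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- if (!is.null(config$input)) {
    read_cohort(config$input, strict = config$strict)
  } else {
    generate_cohort(config$params, seed = config$seed %||% config$params$seed)
  }
  subset <- if (config$subset_ovarian) cohort$ovarian == 1 else NULL
  analysis <- triage_analysis(cohort, thresholds = config$thresholds,
                              method = config$method, level = config$level,
                              subgroups = config$subgroups, subset = subset)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  path <- function(f) file.path(config$out_dir, f)

  utils::write.csv(analysis$metrics, path("overall_metrics.csv"),
                   row.names = FALSE, na = "")
  files <- c(files, path("overall_metrics.csv"))
  writeLines(render_table(analysis$metrics, style = "text"),
             path("overall_metrics.txt"))
  files <- c(files, path("overall_metrics.txt"))
  for (g in names(analysis$subgroups)) {
    f <- path(sprintf("subgroup_%s.csv", g))
    utils::write.csv(as.data.frame(analysis$subgroups[[g]]), f,
                     row.names = FALSE, na = "")
    files <- c(files, f)
  }
  utils::write.csv(analysis$predictions, path("predictions.csv"),
                   row.names = FALSE, na = "")
  files <- c(files, path("predictions.csv"))

  dropped <- attr(cohort, "validation_log")
  manifest <- list(
    seed = config$seed,
    input = config$input %||% "generated",
    config = list(method = config$method, level = config$level,
                  thresholds = unclass(config$thresholds),
                  subgroups = config$subgroups,
                  subset_ovarian = config$subset_ovarian),
    cohort_size = analysis$cohort_size,
    n_analysed = analysis$n_analysed,
    n_dropped_invalid = if (is.null(dropped)) 0L else
      length(unique(dropped$patient_id)),
    evaluable_per_strategy = as.list(analysis$evaluable),
    non_evaluable_reasons = lapply(analysis$reasons, as.list))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  files <- c(files, path("manifest.json"))

  invisible(list(cohort = cohort, analysis = analysis, files = files))
}

#' Render a metrics table
#'
#' Formats a metrics data frame (the `metrics` component of a
#' [triage_analysis()] or a [subgroup_analysis()] result) either as
#' aligned text with `"point% (low–high%)"` entries, percentages
#' rounded half-up to one decimal place (display only — nothing downstream
#' consumes the rounded values), or as CSV lines carrying the same numbers.
#'
#' @param metrics data frame with `metric`, `numerator`, `denominator`,
#'   `estimate`, `lower`, `upper` columns (plus optional `strategy`,
#'   `group`).
#' @param style `"text"` or `"csv"`.
#' @return character vector of table lines.
#' @export
render_table <- function(metrics, style = c("text", "csv")) {
  style <- match.arg(style)
  df <- as.data.frame(metrics)
  if (nrow(df) == 0) return(character())
  df$formatted <- ifelse(is.na(df$estimate), "undefined",
                         fmt_est_ci(df$numerator, df$denominator,
                                    df$lower, df$upper))
  id_cols <- intersect(c("grouping", "group", "strategy", "metric"),
                       names(df))
  out <- df[c(id_cols, "numerator", "denominator", "formatted")]
  out[] <- lapply(out, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- ""
    col
  })
  if (style == "csv") {
    tc <- textConnection("csvbuf", "w", local = TRUE)
    utils::write.csv(out, tc, row.names = FALSE)
    close(tc)
    return(csvbuf)
  }
  widths <- vapply(names(out), function(cn)
    max(nchar(c(cn, as.character(out[[cn]])))), numeric(1))
  fmt_row <- function(vals)
    paste(mapply(formatC, as.character(vals), width = widths,
                 MoreArgs = list(flag = "-")), collapse = "  ")
  c(fmt_row(names(out)), vapply(seq_len(nrow(out)),
                                function(i) fmt_row(out[i, ]), character(1)))
}
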