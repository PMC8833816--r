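#' Cohort data model
#'
#' A triage cohort is a data frame with one row per woman scheduled for
#' surgery for a pelvic mass, carrying her serum markers, the ultrasound
#' features needed by the IOTA simple rules and the RMI, an optional expert
#' ultrasound call, and the histology reference standard.  The reference
#' truth for every evaluation in this package is *malignant including
#' borderline tumours*: a record counts as diseased when `histology` is
#' `"borderline"` or `"malignant"`.
#'
#' Columns (flags are 0/1 integers, missing values empty cells in CSV):
#'
#' * `patient_id` — unique opaque identifier.
#' * `age` — years.
#' * `menopausal` — `"pre"` or `"post"`.
#' * `ca125` — serum CA125, U/mL, non-negative.
#' * `he4` — serum HE4, pmol/L, non-negative; may be missing.
#' * B-features: `b_unilocular`, `b_solid_lt7mm` (largest solid component
#'   < 7 mm), `b_acoustic_shadows`, `b_smooth_multiloc_lt100` (smooth
#'   multilocular tumour < 100 mm), `b_no_flow` (colour score 1).
#' * M-features: `m_irregular_solid`, `m_ascites`, `m_papillary_ge4` (at
#'   least four papillary structures), `m_irregular_multiloc_solid_ge100`
#'   (irregular multilocular solid tumour >= 100 mm), `m_strong_flow`
#'   (colour score 4).
#' * `colour_score` — IOTA colour Doppler score, integer 1-4.
#' * RMI features: `rmi_multilocular`, `rmi_solid_areas`, `rmi_metastases`,
#'   `rmi_ascites`, `rmi_bilateral`; may be missing (RMI then unavailable).
#' * `expert_call` — `"malignant"`/`"benign"` subjective expert assessment;
#'   may be missing.
#' * `histology` — `"benign"`, `"borderline"` or `"malignant"`.
#' * `ovarian` — 0/1 flag, mass of ovarian origin.
#' * `site` — `"cancer_centre"` or `"general_unit"`.
#' * `figo_stage` — `"I"`, `"II"`, `"III"`, `"IV"` or `"unstaged"`; only
#'   for borderline/malignant histology, may be missing.
#'
#' @name triage_cohort
NULL

B_FEATURES <- c("b_unilocular", "b_solid_lt7mm", "b_acoustic_shadows",
                "b_smooth_multiloc_lt100", "b_no_flow")
M_FEATURES <- c("m_irregular_solid", "m_ascites", "m_papillary_ge4",
                "m_irregular_multiloc_solid_ge100", "m_strong_flow")
RMI_FEATURES <- c("rmi_multilocular", "rmi_solid_areas", "rmi_metastases",
                  "rmi_ascites", "rmi_bilateral")

COHORT_COLUMNS <- c("patient_id", "age", "menopausal", "ca125", "he4",
                    B_FEATURES, M_FEATURES, "colour_score", RMI_FEATURES,
                    "expert_call", "histology", "ovarian", "site",
                    "figo_stage")

# columns whose values must never be missing (header must always be complete)
MANDATORY_VALUES <- c("patient_id", "age", "menopausal", "ca125",
                      B_FEATURES, M_FEATURES, "colour_score",
                      "histology", "ovarian", "site")

FIGO_LEVELS <- c("I", "II", "III", "IV", "unstaged")

#' Construct a triage cohort from a data frame
#'
#' @param data data frame with the columns documented in [triage_cohort].
#' @param provenance free-text provenance (file path, generator seed, ...).
#' @param strict if `TRUE` (default) any record-level violation is an error;
#'   otherwise invalid records are dropped and reported in the
#'   `"validation_log"` attribute.
#' @return a `triage_cohort` data frame.
#' @export
as_triage_cohort <- function(data, provenance = "in-memory", strict = TRUE) {
  missing_cols <- setdiff(COHORT_COLUMNS, names(data))
  if (length(missing_cols) > 0)
    stopf("cohort is missing mandatory columns: %s",
          paste(missing_cols, collapse = ", "))
  data <- as.data.frame(data)[COHORT_COLUMNS]
  data$patient_id <- as.character(data$patient_id)
  for (col in c("age", "ca125", "he4"))
    data[[col]] <- as.numeric(data[[col]])
  for (col in c(B_FEATURES, M_FEATURES, RMI_FEATURES,
                "colour_score", "ovarian"))
    data[[col]] <- as.integer(data[[col]])
  for (col in c("menopausal", "expert_call", "histology", "site",
                "figo_stage"))
    data[[col]] <- as.character(data[[col]])

  dup <- unique(data$patient_id[duplicated(data$patient_id)])
  if (length(dup) > 0)
    stopf("duplicate patient_id in cohort: %s",
          paste(utils::head(dup, 5), collapse = ", "))

  violations <- validate_cohort(data)
  if (nrow(violations) > 0) {
    if (strict) {
      stopf("cohort fails validation (%d violation%s), e.g.: %s",
            nrow(violations), if (nrow(violations) > 1) "s" else "",
            paste(utils::head(violations$message, 3), collapse = "; "))
    }
    bad_ids <- unique(violations$patient_id)
    data <- data[!data$patient_id %in% bad_ids, , drop = FALSE]
  }
  rownames(data) <- NULL
  structure(data,
            provenance = provenance,
            validation_log = violations,
            class = c("triage_cohort", "data.frame"))
}

#' Validate a single patient record
#'
#' Checks every record-level invariant of the data model and returns the
#' violations as data rather than raising conditions, so validation is total.
#'
#' @param record one-row data frame (or list) with the cohort columns.
#' @return character vector of violation messages, empty if valid.
#' @export
validate_record <- function(record) {
  v <- validate_cohort(as.data.frame(record, stringsAsFactors = FALSE))
  v$message
}

#' Validate all records of a cohort
#'
#' @param data data frame with the cohort columns.
#' @return data frame with columns `patient_id`, `field`, `message` (one row
#'   per violation; zero rows if the cohort is valid).
#' @export
validate_cohort <- function(data) {
  out <- list()
  add <- function(bad, field, rule) {
    bad[is.na(bad)] <- TRUE   # NA in a checked expression is itself invalid
    if (any(bad))
      out[[length(out) + 1]] <<- data.frame(
        patient_id = as.character(data$patient_id[bad]),
        field = field,
        message = sprintf("%s: %s [%s]", data$patient_id[bad], field, rule),
        stringsAsFactors = FALSE)
  }
  chk_flag <- function(field, required) {
    x <- data[[field]]
    bad <- !is.na(x) & !x %in% c(0L, 1L)
    if (required) bad <- bad | is.na(x)
    add(bad, field, "flag must be 0 or 1")
  }

  add(is.na(data$patient_id) | data$patient_id == "", "patient_id",
      "must be non-empty")
  add(is.na(data$age) | data$age < 0, "age", "must be a non-negative number")
  add(!data$menopausal %in% c("pre", "post"), "menopausal",
      "must be 'pre' or 'post'")
  add(is.na(data$ca125) | data$ca125 < 0, "ca125", "must be >= 0 U/mL")
  add(!is.na(data$he4) & data$he4 < 0, "he4", "must be >= 0 pmol/L")
  for (f in c(B_FEATURES, M_FEATURES)) chk_flag(f, required = TRUE)
  for (f in RMI_FEATURES) chk_flag(f, required = FALSE)
  add(!data$colour_score %in% 1:4, "colour_score", "must be 1, 2, 3 or 4")
  add(data$b_no_flow == 1 & data$colour_score != 1, "b_no_flow",
      "b_no_flow implies colour_score 1")
  add(data$m_strong_flow == 1 & data$colour_score != 4, "m_strong_flow",
      "m_strong_flow implies colour_score 4")
  add(data$b_no_flow == 1 & data$m_strong_flow == 1, "b_no_flow",
      "flow flags are mutually exclusive")
  both <- !is.na(data$m_ascites) & !is.na(data$rmi_ascites)
  add(both & data$m_ascites != data$rmi_ascites, "rmi_ascites",
      "m_ascites and rmi_ascites must agree when both recorded")
  add(!is.na(data$expert_call) &
        !data$expert_call %in% c("malignant", "benign"), "expert_call",
      "must be 'malignant' or 'benign'")
  add(!data$histology %in% c("benign", "borderline", "malignant"),
      "histology", "must be benign, borderline or malignant")
  add(!data$ovarian %in% c(0L, 1L), "ovarian", "flag must be 0 or 1")
  add(!data$site %in% c("cancer_centre", "general_unit"), "site",
      "must be 'cancer_centre' or 'general_unit'")
  add(!is.na(data$figo_stage) & !data$figo_stage %in% FIGO_LEVELS,
      "figo_stage", "must be I, II, III, IV or unstaged")
  add(!is.na(data$figo_stage) & !is.na(data$histology) &
        data$histology == "benign", "figo_stage",
      "present only for borderline/malignant histology")

  if (length(out) == 0)
    return(data.frame(patient_id = character(), field = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Read a cohort from CSV
#'
#' @param path CSV file with the documented header; flags 0/1, missing values
#'   as empty cells.
#' @param strict passed to [as_triage_cohort()]: error on any invalid record
#'   (default) or drop invalid records and log them.
#' @return a `triage_cohort`; in non-strict mode the `"validation_log"`
#'   attribute lists dropped records.
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stopf("cohort file does not exist: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "")
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols) > 0)
    stopf("cohort CSV %s is missing mandatory columns: %s", path,
          paste(missing_cols, collapse = ", "))
  as_triage_cohort(raw, provenance = path, strict = strict)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: the written file reproduces every field
#' (missing values as empty cells), so read-after-write is the identity on
#' valid cohorts up to float formatting.
#'
#' @param cohort a `triage_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort)[COHORT_COLUMNS], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.triage_cohort <- function(x, ...) {
  truth <- truth_malignant(x)
  cat(sprintf(
    "Triage cohort: %d records (%d malignant incl. borderline, %.1f%%)\n",
    nrow(x), sum(truth), if (nrow(x) > 0) 100 * mean(truth) else NA_real_))
  cat(sprintf("Provenance: %s\n", attr(x, "provenance") %||% "unknown"))
  log <- attr(x, "validation_log")
  if (!is.null(log) && nrow(log) > 0)
    cat(sprintf("Dropped records with violations: %d\n",
                length(unique(log$patient_id))))
  invisible(x)
}

#' Reference-standard truth label
#'
#' The evaluation truth is "malignant" if and only if histology is borderline
#' or malignant (borderline tumours count as malignant).
#'
#' @param cohort a `triage_cohort` (or data frame with a `histology` column).
#' @return logical vector, `TRUE` for diseased records.
#' @export
truth_malignant <- function(cohort) {
  cohort$histology %in% c("borderline", "malignant")
}
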