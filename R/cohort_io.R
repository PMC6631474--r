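#' Construct a concentration matrix
#'
#' Samples-by-analytes concentrations (μmol/L) with per-sample metadata and an
#' explicit missing-value convention (`NA`).
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   analytes in columns (colnames = lipid labels).
#' @param samples data frame of sample metadata; must contain `sample_id`
#'   matching the rownames of `values`. Recognised optional columns:
#'   `subject`, `timepoint`, `cohort`, `challenge`, `phase`, `sex`, `group`,
#'   `run_day`.
#' @param platform `"species_level_kit"` or `"fatty_acid_level"`.
#' @return an object of class `concentration_matrix`.
#' @export
concentration_matrix <- function(values, samples,
                                 platform = c("species_level_kit",
                                              "fatty_acid_level")) {
  platform <- match.arg(platform)
  abort_if(!is.matrix(values) || !is.numeric(values),
           "values must be a numeric matrix")
  abort_if(is.null(rownames(values)) || is.null(colnames(values)),
           "values must have sample ids as rownames and analyte labels as colnames")
  abort_if(!"sample_id" %in% names(samples),
           "sample metadata must contain a sample_id column")
  samples$sample_id <- as.character(samples$sample_id)
  abort_if(anyDuplicated(samples$sample_id) > 0, "duplicate sample_id")
  abort_if(!identical(sort(samples$sample_id), sort(rownames(values))),
           "sample metadata does not match matrix rows")
  samples <- samples[match(rownames(values), samples$sample_id), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  abort_if(any(values < 0, na.rm = TRUE),
           "negative concentrations are not allowed")
  expected_res <- if (platform == "species_level_kit") "sum_level" else
    "fatty_acid_level"
  for (lab in colnames(values)) {
    e <- parse_lipid_name(lab)
    abort_if(platform == "fatty_acid_level" &&
               e$resolution != "fatty_acid_level",
             "analyte '%s' is not at fatty-acid resolution", lab)
    abort_if(platform == "species_level_kit" &&
               !e$resolution %in% c("sum_level", "species_level"),
             "analyte '%s' is not a kit/species-level label", lab)
  }
  structure(list(values = values, samples = samples,
                 analytes = colnames(values), platform = platform),
            class = "concentration_matrix")
}

#' @export
print.concentration_matrix <- function(x, ...) {
  cat(sprintf("<concentration matrix> %d samples x %d analytes [%s], %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$platform,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.concentration_matrix <- function(x) dim(x$values)

#' Read a concentration table from delimited text
#'
#' Expects one row per sample, metadata columns first (named via
#' `metadata_columns`), then one column per analyte with the lipid label as
#' header. Blank and `NA` cells become missing values. Labels are validated
#' through the shorthand parser.
#'
#' @param path file path (TSV by default; `.csv` files are read as CSV).
#' @param platform `"species_level_kit"` or `"fatty_acid_level"`.
#' @param metadata_columns names of the leading metadata columns present in
#'   the file; must include `sample_id`.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return a [concentration_matrix()].
#' @export
read_concentration_table <- function(path,
                                     platform = c("species_level_kit",
                                                  "fatty_acid_level"),
                                     metadata_columns = c("sample_id",
                                                          "subject",
                                                          "timepoint"),
                                     sep = NULL) {
  platform <- match.arg(platform)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          quote = "\"", comment.char = "")
  missing_meta <- setdiff(metadata_columns, names(df))
  abort_if(length(missing_meta) > 0, "metadata column(s) not in file: %s",
           paste(missing_meta, collapse = ", "))
  analyte_cols <- setdiff(names(df), metadata_columns)
  abort_if(length(analyte_cols) == 0, "no analyte columns found")
  for (lab in analyte_cols) {
    parsed <- tryCatch(parse_lipid_name(lab), error = function(e) e)
    abort_if(inherits(parsed, "error"),
             "column '%s' is not a parseable lipid label: %s", lab,
             conditionMessage(parsed))
  }
  values <- as.matrix(df[analyte_cols])
  storage.mode(values) <- "double"
  rownames(values) <- as.character(df$sample_id)
  concentration_matrix(values, df[metadata_columns], platform)
}

#' Quality-control configuration
#'
#' @param cv_exclude_threshold analytes with reference-sample CV above this
#'   are excluded outright (default 0.25).
#' @param cv_runday_threshold analytes with CV above this *and* a significant
#'   run-day correlation are excluded (default 0.20).
#' @param runday_alpha significance level of the run-day correlation test.
#' @param coverage_min minimum fraction of non-missing samples for
#'   [coverage_filter()] (default 0.25, inclusive).
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(cv_exclude_threshold = 0.25, cv_runday_threshold = 0.20,
                      runday_alpha = 0.05, coverage_min = 0.25) {
  vals <- c(cv_exclude_threshold, cv_runday_threshold, runday_alpha,
            coverage_min)
  abort_if(any(vals < 0 | vals > 1), "qc_config thresholds must lie in [0, 1]")
  structure(list(cv_exclude_threshold = cv_exclude_threshold,
                 cv_runday_threshold = cv_runday_threshold,
                 runday_alpha = runday_alpha, coverage_min = coverage_min),
            class = "qc_config")
}

#' Analyte-level quality-control filter
#'
#' Applies the two reference-sample QC rules: (1) exclude analytes whose
#' coefficient of variation (CV = sd/mean) across reference-plasma replicates
#' exceeds `cv_exclude_threshold`; (2) additionally exclude analytes with CV
#' above `cv_runday_threshold` that show a significant rank correlation with
#' the run day (two-sided Spearman test at `runday_alpha`). Rule 2 is applied
#' only when `run_day` is supplied.
#'
#' @param matrix a [concentration_matrix()].
#' @param reference_values numeric matrix of reference-sample replicate
#'   measurements (replicates in rows), with colnames covering the analytes
#'   of `matrix`.
#' @param config a [qc_config()].
#' @param run_day optional numeric/integer run-day index per reference
#'   replicate (same length as `nrow(reference_values)`); required for rule 2.
#' @return a list with elements `matrix` (filtered) and `report` (data frame
#'   with analyte, cv, runday_p, rule, decision).
#' @export
qc_filter <- function(matrix, reference_values, config = qc_config(),
                      run_day = NULL) {
  stopifnot(inherits(matrix, "concentration_matrix"))
  abort_if(is.null(colnames(reference_values)),
           "reference_values needs analyte colnames")
  missing_ref <- setdiff(matrix$analytes, colnames(reference_values))
  abort_if(length(missing_ref) > 0,
           "no reference replicate values for analyte(s): %s",
           paste(missing_ref, collapse = ", "))
  if (!is.null(run_day)) {
    abort_if(length(run_day) != nrow(reference_values),
             "run_day must have one entry per reference replicate")
  }
  report <- data.frame(analyte = matrix$analytes, cv = NA_real_,
                       runday_p = NA_real_, rule = "", decision = "retained",
                       stringsAsFactors = FALSE)
  for (i in seq_along(matrix$analytes)) {
    v <- reference_values[, matrix$analytes[i]]
    v <- v[!is.na(v)]
    cv <- stats::sd(v) / mean(v)
    report$cv[i] <- cv
    if (is.finite(cv) && cv > config$cv_exclude_threshold) {
      report$rule[i] <- sprintf("CV>%g%%", 100 * config$cv_exclude_threshold)
      report$decision[i] <- "removed"
      next
    }
    if (!is.null(run_day)) {
      keep <- !is.na(reference_values[, matrix$analytes[i]])
      p <- suppressWarnings(stats::cor.test(
        reference_values[keep, matrix$analytes[i]], run_day[keep],
        method = "spearman", alternative = "two.sided"))$p.value
      report$runday_p[i] <- p
      if (is.finite(cv) && cv > config$cv_runday_threshold &&
          is.finite(p) && p < config$runday_alpha) {
        report$rule[i] <- sprintf("CV>%g%% & run-day correlation",
                                  100 * config$cv_runday_threshold)
        report$decision[i] <- "removed"
      }
    }
  }
  keep <- report$decision == "retained"
  out <- matrix
  out$values <- matrix$values[, keep, drop = FALSE]
  out$analytes <- matrix$analytes[keep]
  list(matrix = out, report = report)
}

#' Coverage filter
#'
#' Retains analytes quantified (non-missing) in at least `coverage_min` of
#' the samples; the threshold is inclusive.
#'
#' @param matrix a [concentration_matrix()].
#' @param coverage_min minimum fraction of non-missing samples.
#' @return the filtered [concentration_matrix()].
#' @export
coverage_filter <- function(matrix, coverage_min = 0.25) {
  stopifnot(inherits(matrix, "concentration_matrix"))
  coverage <- colMeans(!is.na(matrix$values))
  keep <- coverage >= coverage_min
  out <- matrix
  out$values <- matrix$values[, keep, drop = FALSE]
  out$analytes <- matrix$analytes[keep]
  out
}
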