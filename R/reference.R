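#' Load the reference composition table
#'
#' Reads (by default) the packaged reference composition of 38
#' phosphatidylcholine sums by 69 measured fatty-acid-level constituents,
#' with per-constituent mean proportions (mean_q), 5%/95% percentile
#' intervals, composition categories and the per-sum explained variance of
#' the through-origin model (R², percent). The table is validated on load:
#' schema, row/sum counts, percentile ordering, category consistency with the
#' strict 0.2/0.8 thresholds, per-sum consistency of `sum_of_proportions`
#' with the member proportions (within rounding of 4-decimal values), and
#' agreement of each printed neutral mass with the nominal mass computed from
#' the species label.
#'
#' @param path optional path to a TSV with the same schema; `NULL` loads the
#'   packaged table.
#' @return a data frame of class `reference_composition`.
#' @examples
#' ref <- load_reference()
#' length(unique(ref$kit_label))  # 38 PC sums
#' @export
load_reference <- function(path = NULL) {
  packaged <- is.null(path)
  if (packaged) {
    path <- system.file("extdata", "reference_composition.tsv",
                        package = "pccomp")
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = TRUE,
                           quote = "\"", comment.char = "")
  schema <- c("species_label", "neutral_mass", "kit_label", "constituent",
              "r_squared_pct", "mean_q", "ci5", "ci95", "category",
              "sum_of_proportions")
  missing_cols <- setdiff(schema, names(tab))
  abort_if(length(missing_cols) > 0, "reference table lacks column(s): %s",
           paste(missing_cols, collapse = ", "))
  tab <- tab[schema]
  # keep the verbatim label but match on the canonical (sorted-chain) form
  tab$constituent_printed <- tab$constituent
  tab$constituent <- vapply(tab$constituent, function(l) {
    format_lipid_name(parse_lipid_name(l), "fatty_acid")
  }, character(1), USE.NAMES = FALSE)

  for (i in seq_len(nrow(tab))) {
    row_id <- sprintf("row %d (%s / %s)", i, tab$kit_label[i],
                      tab$constituent[i])
    sum_e <- parse_lipid_name(tab$kit_label[i])
    abort_if(sum_e$resolution != "sum_level",
             "%s: kit_label is not a kit sum label", row_id)
    cons_e <- parse_lipid_name(tab$constituent[i])
    abort_if(cons_e$resolution != "fatty_acid_level",
             "%s: constituent is not at fatty-acid resolution", row_id)
    spec_e <- parse_lipid_name(tab$species_label[i])
    abort_if(nominal_mass(sum_formula(spec_e)) != tab$neutral_mass[i],
             "%s: printed neutral mass %d does not match computed nominal mass",
             row_id, tab$neutral_mass[i])
    abort_if(tab$ci5[i] > tab$ci95[i], "%s: ci5 exceeds ci95", row_id)
    abort_if(tab$category[i] != proportion_category(tab$mean_q[i]),
             "%s: category '%s' inconsistent with mean_q %.4f", row_id,
             tab$category[i], tab$mean_q[i])
  }
  # per-sum invariants; tolerance covers 4-decimal rounding of the printed
  # member values (and one printed sum that is off by 0.001 from its members)
  for (s in unique(tab$kit_label)) {
    idx <- tab$kit_label == s
    sp <- unique(tab$sum_of_proportions[idx])
    abort_if(length(sp) != 1L,
             "sum '%s': sum_of_proportions differs between rows", s)
    abort_if(abs(sp - sum(tab$mean_q[idx])) > 2e-3,
             "sum '%s': sum_of_proportions %.4f inconsistent with member proportions (sum %.4f)",
             s, sp, sum(tab$mean_q[idx]))
    abort_if(length(unique(tab$r_squared_pct[idx])) != 1L,
             "sum '%s': r_squared_pct differs between rows", s)
  }
  if (packaged) {
    abort_if(length(unique(tab$kit_label)) != 38L,
             "packaged reference must contain 38 PC sums, found %d",
             length(unique(tab$kit_label)))
    abort_if(nrow(tab) != 69L,
             "packaged reference must contain 69 constituent rows, found %d",
             nrow(tab))
  }
  attr(tab, "provenance") <- if (packaged) "packaged" else path
  class(tab) <- c("reference_composition", "data.frame")
  tab
}

#' Summary statistics of a reference composition table
#'
#' Computes the headline counts and statistics of a reference table: numbers
#' of sums with at least one constituent proportion above 0.2, with at least
#' two above 0.2, with a major component above 0.8 (a sum with several counts
#' once), with sum of proportions inside the closed 80–120% band or above
#' 1.2; median, mean and SD of the per-sum R² column (percent); and the mean
#' proportion over the acyl-alkyl ("PC ae") rows whose measured constituent
#' carries an odd-numbered fatty acid chain.
#'
#' @param table a `reference_composition` from [load_reference()], or any
#'   data frame with the same schema.
#' @return a named list of summary values.
#' @export
summarize_reference <- function(table) {
  per_sum <- split(table, table$kit_label)
  max_q <- vapply(per_sum, function(d) max(d$mean_q), numeric(1))
  n_gt02 <- vapply(per_sum, function(d) sum(d$mean_q > 0.2), numeric(1))
  sum_prop <- vapply(per_sum, function(d) d$sum_of_proportions[1], numeric(1))
  r2 <- vapply(per_sum, function(d) d$r_squared_pct[1], numeric(1))

  is_ae <- grepl("^PC ae ", table$kit_label)
  odd_chain <- vapply(table$constituent, function(l) {
    e <- parse_lipid_name(l)
    any(vapply(e$chains, `[[`, integer(1), "carbons") %% 2L == 1L)
  }, logical(1))

  list(
    n_sums = length(per_sum),
    n_constituents = nrow(table),
    n_sums_with_constituent_gt_0.2 = sum(max_q > 0.2),
    n_sums_with_two_constituents_gt_0.2 = sum(n_gt02 >= 2),
    n_sums_with_major_gt_0.8 = sum(max_q > 0.8),
    n_sums_sum_prop_80_120 = sum(sum_prop >= 0.8 & sum_prop <= 1.2),
    n_sums_sum_prop_gt_1.2 = sum(sum_prop > 1.2),
    r_squared_median = stats::median(r2),
    r_squared_mean = mean(r2),
    r_squared_sd = stats::sd(r2),
    mean_q_ae_odd_chain = mean(table$mean_q[is_ae & odd_chain])
  )
}

#' Impute fatty-acid-level PC concentrations from PC sums
#'
#' Applies the reference proportions to a species-level kit matrix: for each
#' sample and each (sum i, constituent j) pair of the reference table, the
#' imputed concentration is mean_q(i, j) x conc(i) (μmol/L). Missing sum
#' concentrations propagate to missing imputed values. Sums of the input
#' matrix absent from the reference are skipped with a warning. The result
#' carries an `imputed` provenance flag.
#'
#' @param species_matrix species-level kit [concentration_matrix()].
#' @param table reference table from [load_reference()].
#' @return a fatty-acid-level [concentration_matrix()] of imputed values,
#'   with `attr(, "imputed") = TRUE` and the applied proportions in
#'   `attr(, "imputation_weights")`.
#' @examples
#' ref <- load_reference()
#' m <- concentration_matrix(
#'   matrix(1, 1, 1, dimnames = list("s1", "PC aa C36:2")),
#'   data.frame(sample_id = "s1"), "species_level_kit")
#' impute_constituents(m, ref)$values
#' @export
impute_constituents <- function(species_matrix, table) {
  stopifnot(inherits(species_matrix, "concentration_matrix"))
  abort_if(species_matrix$platform != "species_level_kit",
           "imputation starts from a species-level kit matrix")
  kit_map <- kit_label_map(species_matrix)
  known <- names(kit_map)[names(kit_map) %in% unique(table$kit_label)]
  skipped <- setdiff(names(kit_map), known)
  if (length(skipped)) {
    warning(sprintf("no reference composition for: %s",
                    paste(skipped, collapse = ", ")), call. = FALSE)
  }
  abort_if(length(known) == 0, "no analyte of the matrix is in the reference")

  rows <- table[table$kit_label %in% known, , drop = FALSE]
  out <- matrix(NA_real_, nrow(species_matrix$values), nrow(rows),
                dimnames = list(rownames(species_matrix$values),
                                rows$constituent))
  for (k in seq_len(nrow(rows))) {
    out[, k] <- rows$mean_q[k] *
      species_matrix$values[, kit_map[[rows$kit_label[k]]]]
  }
  res <- concentration_matrix(out, species_matrix$samples,
                              platform = "fatty_acid_level")
  attr(res, "imputed") <- TRUE
  attr(res, "imputation_weights") <-
    rows[c("kit_label", "constituent", "mean_q")]
  res
}
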