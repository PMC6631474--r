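# canonical kit label for each column of a species-level matrix
kit_label_map <- function(species_matrix) {
  labs <- vapply(species_matrix$analytes, function(l) {
    format_lipid_name(parse_lipid_name(l), "kit")
  }, character(1))
  stats::setNames(seq_along(labs), labs)
}

# canonical fatty-acid label for each column of a fatty-acid-level matrix
fa_label_map <- function(fa_matrix) {
  labs <- vapply(fa_matrix$analytes, function(l) {
    format_lipid_name(parse_lipid_name(l), "fatty_acid")
  }, character(1))
  stats::setNames(seq_along(labs), labs)
}

#' Per-sample constituent ratios
#'
#' For every (sum i, measured constituent j) pair defined by the catalogs,
#' divides the fatty-acid-level concentration of j by the species-level
#' concentration of the containing sum i in each sample:
#' q_ijst = conc(PC_j) / conc(PC_i). Samples where either value is missing,
#' or where the denominator is zero, are excluded from that pair.
#'
#' @param species_matrix species-level kit [concentration_matrix()].
#' @param fa_matrix fatty-acid-level [concentration_matrix()].
#' @param catalogs a `constituent_catalog_set` from
#'   [assemble_constituent_catalog()].
#' @return a data frame of class `ratio_sets`, one row per
#'   (sum, constituent, sample) with the ratio `q` and the sample metadata
#'   columns of the species matrix.
#' @export
compute_ratio_set <- function(species_matrix, fa_matrix, catalogs) {
  stopifnot(inherits(species_matrix, "concentration_matrix"),
            inherits(fa_matrix, "concentration_matrix"),
            inherits(catalogs, "constituent_catalog_set"))
  abort_if(species_matrix$platform != "species_level_kit",
           "species_matrix must be on the species_level_kit platform")
  abort_if(fa_matrix$platform != "fatty_acid_level",
           "fa_matrix must be on the fatty_acid_level platform")
  common <- intersect(rownames(species_matrix$values),
                      rownames(fa_matrix$values))
  abort_if(length(common) == 0, "matrices share no sample ids")
  kit_map <- kit_label_map(species_matrix)
  fa_map <- fa_label_map(fa_matrix)

  meta <- species_matrix$samples
  meta <- meta[match(common, meta$sample_id), , drop = FALSE]

  rows <- list()
  for (ct in catalogs) {
    if (!length(ct$measured)) next
    abort_if(!ct$sum_label %in% names(kit_map),
             "catalog sum '%s' has no analyte in the species matrix",
             ct$sum_label)
    denom <- species_matrix$values[common, kit_map[[ct$sum_label]]]
    for (j in ct$measured) {
      abort_if(!j %in% names(fa_map),
               "catalog constituent '%s' has no analyte in the fatty-acid matrix",
               j)
      num <- fa_matrix$values[common, fa_map[[j]]]
      ok <- !is.na(num) & !is.na(denom) & denom > 0
      if (!any(ok)) next
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(sum_label = ct$sum_label, constituent = j,
                   q = num[ok] / denom[ok], stringsAsFactors = FALSE),
        meta[ok, , drop = FALSE])
    }
  }
  abort_if(length(rows) == 0, "no (sum, constituent) pair has usable samples")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ratio_sets", "data.frame")
  out
}

# apply a sample filter (predicate on metadata, or sample_id vector)
apply_sample_filter <- function(ratio_sets, sample_filter) {
  if (is.null(sample_filter)) return(ratio_sets)
  if (is.function(sample_filter)) {
    keep <- sample_filter(ratio_sets)
    abort_if(!is.logical(keep) || length(keep) != nrow(ratio_sets),
             "sample_filter function must return one logical per row")
  } else {
    keep <- ratio_sets$sample_id %in% sample_filter
  }
  out <- ratio_sets[keep, , drop = FALSE]
  class(out) <- class(ratio_sets)
  out
}

# composition category: strict thresholds at 0.2 and 0.8
proportion_category <- function(mean_q) {
  ifelse(mean_q > 0.8, "II", ifelse(mean_q > 0.2, "I", "none"))
}

#' Summarize characteristic compositions of PC sums
#'
#' Aggregates per-sample ratios into one estimate per (sum, constituent):
#' the mean ratio, empirical 5th/95th percentiles (linear interpolation
#' between order statistics), a composition category (`"II"` if the mean
#' exceeds 0.8, `"I"` if it exceeds 0.2, else `"none"`), the sum of
#' proportions over all measured constituents of the sum, and a main-
#' constituent flag (largest mean; ties broken by label order).
#'
#' @param ratio_sets output of [compute_ratio_set()].
#' @param sample_filter optional filter: a character vector of sample ids to
#'   keep, or a predicate function mapping the ratio rows to a logical vector
#'   (e.g. a metadata restriction).
#' @return a data frame of class `sum_composition` with one row per
#'   (sum_label, constituent): `n_used`, `mean_q`, `ci5`, `ci95`, `category`,
#'   `is_main`, `sum_of_proportions`.
#' @export
summarize_composition <- function(ratio_sets, sample_filter = NULL) {
  stopifnot(inherits(ratio_sets, "ratio_sets"))
  rs <- apply_sample_filter(ratio_sets, sample_filter)
  abort_if(nrow(rs) == 0, "no ratios left after filtering")

  key <- interaction(rs$sum_label, rs$constituent, drop = TRUE)
  parts <- split(rs, key)
  est <- do.call(rbind, lapply(parts, function(d) {
    qs <- stats::quantile(d$q, c(0.05, 0.95), names = FALSE, type = 7)
    data.frame(sum_label = d$sum_label[1], constituent = d$constituent[1],
               n_used = nrow(d), mean_q = mean(d$q), ci5 = qs[1],
               ci95 = qs[2], stringsAsFactors = FALSE)
  }))
  est$category <- proportion_category(est$mean_q)
  est <- est[order(est$sum_label, est$constituent), , drop = FALSE]

  est$is_main <- FALSE
  est$sum_of_proportions <- NA_real_
  for (s in unique(est$sum_label)) {
    idx <- which(est$sum_label == s)
    est$sum_of_proportions[idx] <- sum(est$mean_q[idx])
    # ties on mean_q resolved by canonical label order (rows sorted above)
    est$is_main[idx[which.max(est$mean_q[idx])]] <- TRUE
  }
  rownames(est) <- NULL
  class(est) <- c("sum_composition", "data.frame")
  est
}

#' Within-platform constituent fractions
#'
#' For each sum and sample, the fraction of each measured constituent among
#' the measured constituents only, using the side-chain resolving platform
#' alone: conc_j / sum over measured constituents of the sum. Samples in
#' which some (but not all) constituents are missing are computed over the
#' remaining ones and flagged `partial`; samples with an all-missing or
#' all-zero denominator yield `NA`.
#'
#' @param fa_matrix fatty-acid-level [concentration_matrix()].
#' @param catalogs a `constituent_catalog_set`.
#' @return data frame with columns sample_id, sum_label, constituent,
#'   fraction, partial.
#' @export
lipidyzer_fractions <- function(fa_matrix, catalogs) {
  stopifnot(inherits(fa_matrix, "concentration_matrix"),
            inherits(catalogs, "constituent_catalog_set"))
  fa_map <- fa_label_map(fa_matrix)
  rows <- list()
  for (ct in catalogs) {
    if (!length(ct$measured)) next
    missing_cols <- setdiff(ct$measured, names(fa_map))
    abort_if(length(missing_cols) > 0,
             "catalog constituent(s) absent from matrix: %s",
             paste(missing_cols, collapse = ", "))
    sub <- fa_matrix$values[, fa_map[ct$measured], drop = FALSE]
    denom <- rowSums(sub, na.rm = TRUE)
    n_obs <- rowSums(!is.na(sub))
    denom[n_obs == 0 | denom == 0] <- NA
    partial <- n_obs > 0 & n_obs < length(ct$measured)
    for (k in seq_along(ct$measured)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = rownames(fa_matrix$values), sum_label = ct$sum_label,
        constituent = ct$measured[k], fraction = sub[, k] / denom,
        partial = partial, stringsAsFactors = FALSE)
    }
  }
  abort_if(length(rows) == 0, "no catalog has measured constituents")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
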