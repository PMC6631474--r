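# complete-case sum / cumulated-constituent vectors for one catalog
concordance_vectors <- function(species_matrix, fa_matrix, catalog) {
  stopifnot(inherits(catalog, "constituent_catalog"))
  abort_if(!length(catalog$measured),
           "catalog '%s' has no measured constituents", catalog$sum_label)
  common <- intersect(rownames(species_matrix$values),
                      rownames(fa_matrix$values))
  abort_if(length(common) == 0, "matrices share no sample ids")
  kit_map <- kit_label_map(species_matrix)
  fa_map <- fa_label_map(fa_matrix)
  abort_if(!catalog$sum_label %in% names(kit_map),
           "sum '%s' absent from the species matrix", catalog$sum_label)
  missing_fa <- setdiff(catalog$measured, names(fa_map))
  abort_if(length(missing_fa) > 0,
           "constituent(s) absent from the fatty-acid matrix: %s",
           paste(missing_fa, collapse = ", "))
  y <- species_matrix$values[common, kit_map[[catalog$sum_label]]]
  sub <- fa_matrix$values[common, fa_map[catalog$measured], drop = FALSE]
  # complete-case: the cumulated constituent sum is never partial
  ok <- !is.na(y) & rowSums(is.na(sub)) == 0
  list(y = unname(y[ok]), x = unname(rowSums(sub[ok, , drop = FALSE])),
       sample_id = common[ok])
}

#' Through-origin proportional fit of a PC sum on its constituents
#'
#' Least-squares fit of the species-level sum concentration on the cumulated
#' measured fatty-acid-level constituents without an intercept:
#' conc(sum) ~ b * sum(conc(constituents)). Only complete cases (sum and all
#' measured constituents present) enter the fit. By default the reported R²
#' is the squared Pearson correlation between observed and fitted values
#' (centred definition); the uncentred no-intercept variant
#' 1 - RSS / sum(y²) is available via `r_squared`.
#'
#' @param species_matrix species-level kit [concentration_matrix()].
#' @param fa_matrix fatty-acid-level [concentration_matrix()].
#' @param catalog a single `constituent_catalog` with measured constituents.
#' @param r_squared `"centered"` (default) or `"uncentered"`.
#' @return object of class `proportional_fit`: list with `sum_label`, `b`,
#'   `r_squared`, `r_squared_definition` and `n`.
#' @export
fit_proportional_model <- function(species_matrix, fa_matrix, catalog,
                                   r_squared = c("centered", "uncentered")) {
  r_squared <- match.arg(r_squared)
  v <- concordance_vectors(species_matrix, fa_matrix, catalog)
  abort_if(length(v$y) < 3, "fewer than 3 complete samples for '%s'",
           catalog$sum_label)
  abort_if(stats::sd(v$x) == 0,
           "zero-variance predictor for '%s': fit undefined",
           catalog$sum_label)
  b <- sum(v$x * v$y) / sum(v$x^2)
  fitted <- b * v$x
  r2 <- if (r_squared == "centered") {
    if (stats::sd(v$y) == 0) 0 else stats::cor(v$y, fitted)^2
  } else {
    1 - sum((v$y - fitted)^2) / sum(v$y^2)
  }
  structure(list(sum_label = catalog$sum_label, b = b, r_squared = r2,
                 r_squared_definition = r_squared, n = length(v$y)),
            class = "proportional_fit")
}

#' @export
print.proportional_fit <- function(x, ...) {
  cat(sprintf("<proportional fit> %s: b = %.4f, R^2 = %.1f%% (%s), n = %d\n",
              x$sum_label, x$b, 100 * x$r_squared, x$r_squared_definition,
              x$n))
  invisible(x)
}

#' Bland–Altman concordance of a PC sum and its constituents
#'
#' Per-sample differences d = conc(sum) - sum(conc(constituents)) against
#' per-sample means m = (conc(sum) + sum(conc(constituents))) / 2, over
#' complete cases. The mean difference is classified against the SD of the
#' species-level measure itself: `within_1SD`, `within_2SD`, or
#' `beyond_2SD`; a negative mean difference means the cumulated constituents
#' exceed the sum measure. Conventional limits of agreement
#' (mean ± 1.96 · SD of the differences) are also reported.
#'
#' @inheritParams fit_proportional_model
#' @return object of class `bland_altman`: list with per-sample `difference`
#'   and `mean` vectors, `mean_difference`, `sd_reference`,
#'   `classification`, `sd_differences`, `loa_lower`, `loa_upper`, `n`.
#' @export
bland_altman_stats <- function(species_matrix, fa_matrix, catalog) {
  v <- concordance_vectors(species_matrix, fa_matrix, catalog)
  abort_if(length(v$y) < 2, "fewer than 2 complete samples for '%s'",
           catalog$sum_label)
  d <- v$y - v$x
  m <- (v$y + v$x) / 2
  mean_d <- mean(d)
  sd_ref <- stats::sd(v$y)
  classification <- if (abs(mean_d) <= sd_ref) "within_1SD" else
    if (abs(mean_d) <= 2 * sd_ref) "within_2SD" else "beyond_2SD"
  sd_d <- stats::sd(d)
  structure(list(sum_label = catalog$sum_label, difference = d, mean = m,
                 sample_id = v$sample_id, mean_difference = mean_d,
                 sd_reference = sd_ref, classification = classification,
                 sd_differences = sd_d,
                 loa_lower = mean_d - 1.96 * sd_d,
                 loa_upper = mean_d + 1.96 * sd_d, n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<Bland-Altman> %s: mean difference = %.4f (%s; SD of reference = %.4f), n = %d\n",
              x$sum_label, x$mean_difference, x$classification,
              x$sd_reference, x$n))
  invisible(x)
}

#' Per-sum concordance report
#'
#' Runs [fit_proportional_model()] and [bland_altman_stats()] for every
#' catalog with measured constituents; degenerate sums are recorded with a
#' note instead of failing the whole report.
#'
#' @param species_matrix,fa_matrix paired [concentration_matrix()] objects.
#' @param catalogs a `constituent_catalog_set`.
#' @param r_squared R² definition passed to [fit_proportional_model()].
#' @return data frame with one row per sum: `b`, `r_squared`, `n`,
#'   `mean_difference`, `sd_reference`, `classification`, `note`.
#' @export
concordance_report <- function(species_matrix, fa_matrix, catalogs,
                               r_squared = c("centered", "uncentered")) {
  r_squared <- match.arg(r_squared)
  rows <- list()
  for (ct in catalogs) {
    if (!length(ct$measured)) next
    fit <- tryCatch(fit_proportional_model(species_matrix, fa_matrix, ct,
                                           r_squared = r_squared),
                    error = function(e) e)
    ba <- tryCatch(bland_altman_stats(species_matrix, fa_matrix, ct),
                   error = function(e) e)
    note <- ""
    if (inherits(fit, "error")) note <- conditionMessage(fit)
    if (inherits(ba, "error")) {
      note <- paste(note, conditionMessage(ba), sep = if (nzchar(note))
        "; " else "")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sum_label = ct$sum_label,
      b = if (inherits(fit, "error")) NA_real_ else fit$b,
      r_squared = if (inherits(fit, "error")) NA_real_ else fit$r_squared,
      n = if (inherits(fit, "error")) NA_integer_ else fit$n,
      mean_difference = if (inherits(ba, "error")) NA_real_ else
        ba$mean_difference,
      sd_reference = if (inherits(ba, "error")) NA_real_ else
        ba$sd_reference,
      classification = if (inherits(ba, "error")) NA_character_ else
        ba$classification,
      note = note, stringsAsFactors = FALSE)
  }
  abort_if(length(rows) == 0, "no catalog has measured constituents")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
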