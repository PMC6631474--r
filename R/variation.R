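#' Intra- and inter-individual variation of constituent ratios
#'
#' Restricts the ratio rows to baseline/intervention timepoints of the
#' selected metabolic challenges and computes two averaged standard
#' deviations: `sd_challenges`, the mean over (sum, constituent, subject)
#' cells of the SD of q across that subject's selected timepoints
#' (intra-individual variation), and `sd_subjects`, the mean over
#' (sum, constituent, timepoint) cells of the SD of q across subjects
#' (inter-individual variation). Cells with fewer than two observations are
#' skipped and counted.
#'
#' @param ratio_sets output of [compute_ratio_set()]; rows must carry
#'   `subject`, `timepoint`, `challenge` and `phase` metadata.
#' @param challenges challenge labels to include (default the lipid-related
#'   ones: `"FASTING"`, `"PAT"`, `"OLTT"`).
#' @param phases phases to include (default baseline and intervention).
#' @return an object of class `variation_summary`: list with
#'   `sd_challenges`, `sd_subjects`, per-cell data frames and skip counts.
#' @export
variation_sds <- function(ratio_sets,
                          challenges = c("FASTING", "PAT", "OLTT"),
                          phases = c("baseline", "intervention")) {
  stopifnot(inherits(ratio_sets, "ratio_sets"))
  needed <- c("subject", "timepoint", "challenge", "phase")
  missing_cols <- setdiff(needed, names(ratio_sets))
  abort_if(length(missing_cols) > 0, "ratio rows lack metadata column(s): %s",
           paste(missing_cols, collapse = ", "))
  rs <- ratio_sets[!is.na(ratio_sets$challenge) &
                     ratio_sets$challenge %in% challenges &
                     ratio_sets$phase %in% phases, , drop = FALSE]
  abort_if(nrow(rs) == 0, "no samples at the selected challenge timepoints")

  cell_sds <- function(d, group_col) {
    grp <- interaction(d$sum_label, d$constituent, d[[group_col]],
                       drop = TRUE)
    parts <- split(d$q, grp)
    n <- lengths(parts)
    data.frame(cell = names(parts),
               sd = vapply(parts, function(v)
                 if (length(v) >= 2) stats::sd(v) else NA_real_, numeric(1)),
               n = n, stringsAsFactors = FALSE)
  }
  within_cells <- cell_sds(rs, "subject")      # across timepoints, per subject
  between_cells <- cell_sds(rs, "timepoint")   # across subjects, per timepoint

  structure(list(
    sd_challenges = mean(within_cells$sd, na.rm = TRUE),
    sd_subjects = mean(between_cells$sd, na.rm = TRUE),
    within_cells = within_cells, between_cells = between_cells,
    n_skipped_within = sum(is.na(within_cells$sd)),
    n_skipped_between = sum(is.na(between_cells$sd))),
    class = "variation_summary")
}

#' @export
print.variation_summary <- function(x, ...) {
  cat(sprintf("<variation summary> SD_challenges = %.4f (intra-individual), SD_subjects = %.4f (inter-individual)\n",
              x$sd_challenges, x$sd_subjects))
  invisible(x)
}

# extract the q values of one (sum, constituent) pair
pair_rows <- function(ratio_sets, sum_label, constituent) {
  d <- ratio_sets[ratio_sets$sum_label == sum_label &
                    ratio_sets$constituent == constituent, , drop = FALSE]
  abort_if(nrow(d) == 0, "no ratios for (%s, %s)", sum_label, constituent)
  d
}

#' Paired baseline/intervention test of a constituent ratio
#'
#' Two-sided Wilcoxon signed-rank test of q at the baseline versus the
#' intervention timepoint of one challenge, paired by subject. Subjects
#' missing either arm are dropped with a warning; zero differences are
#' dropped (when all pairs are ties the p-value is 1 by convention); with
#' fewer than two usable pairs the test is skipped (`NA`).
#'
#' @param ratio_sets output of [compute_ratio_set()].
#' @param sum_label,constituent the (i, j) pair to test.
#' @param challenge challenge label whose baseline/intervention samples are
#'   compared.
#' @return list with `n_pairs`, `statistic` and `p_value`.
#' @export
paired_challenge_test <- function(ratio_sets, sum_label, constituent,
                                  challenge) {
  d <- pair_rows(ratio_sets, sum_label, constituent)
  d <- d[!is.na(d$challenge) & d$challenge == challenge, , drop = FALSE]
  base <- d[d$phase == "baseline", c("subject", "q")]
  intv <- d[d$phase == "intervention", c("subject", "q")]
  # one value per subject and arm; average replicates defensively
  base <- stats::aggregate(q ~ subject, base, mean)
  intv <- stats::aggregate(q ~ subject, intv, mean)
  subj <- intersect(base$subject, intv$subject)
  unpaired <- setdiff(union(base$subject, intv$subject), subj)
  if (length(unpaired)) {
    warning(sprintf("dropping unpaired subject(s): %s",
                    paste(unpaired, collapse = ", ")), call. = FALSE)
  }
  if (length(subj) < 2) {
    return(list(n_pairs = length(subj), statistic = NA_real_,
                p_value = NA_real_))
  }
  diffs <- base$q[match(subj, base$subject)] -
    intv$q[match(subj, intv$subject)]
  nz <- diffs[diffs != 0]
  if (length(nz) == 0) {
    return(list(n_pairs = length(subj), statistic = 0, p_value = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(nz, mu = 0,
                                            alternative = "two.sided"))
  list(n_pairs = length(subj), statistic = unname(wt$statistic),
       p_value = wt$p.value)
}

#' Between-subject distribution test with normality gate
#'
#' Compares the distribution of q across subjects for one (sum, constituent)
#' pair. A Shapiro–Wilk test on the within-subject-centred residuals gates
#' the choice of test: one-way ANOVA when normality is not rejected at
#' `normality_alpha`, Kruskal–Wallis otherwise. Degenerate inputs (constant
#' values, or fewer than two subjects with two observations) are skipped.
#'
#' @param ratio_sets output of [compute_ratio_set()].
#' @param sum_label,constituent the (i, j) pair to test.
#' @param normality_alpha level of the Shapiro–Wilk gate (default 0.05).
#' @return list with `test_name` (`"anova"`, `"kruskal"` or `"skipped"`),
#'   `p_value` and `shapiro_p`.
#' @export
across_subject_test <- function(ratio_sets, sum_label, constituent,
                                normality_alpha = 0.05) {
  d <- pair_rows(ratio_sets, sum_label, constituent)
  subj <- factor(d$subject)
  tab <- table(subj)
  if (sum(tab >= 2) < 2 || stats::sd(d$q) == 0) {
    return(list(test_name = "skipped", p_value = NA_real_,
                shapiro_p = NA_real_))
  }
  resid <- d$q - stats::ave(d$q, subj)
  shapiro_p <- if (length(resid) >= 3 && length(resid) <= 5000 &&
                   stats::sd(resid) > 0) {
    stats::shapiro.test(resid)$p.value
  } else NA_real_
  if (!is.na(shapiro_p) && shapiro_p >= normality_alpha) {
    fit <- stats::aov(q ~ subj, data = data.frame(q = d$q, subj = subj))
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    return(list(test_name = "anova", p_value = p, shapiro_p = shapiro_p))
  }
  kw <- stats::kruskal.test(d$q, subj)
  list(test_name = "kruskal", p_value = kw$p.value, shapiro_p = shapiro_p)
}

#' Cohort comparison configuration
#'
#' Bonferroni-corrected significance level for per-sum cohort comparisons:
#' `alpha = alpha_total / n_tests`, with `n_tests` recomputed from the data
#' as the number of sums testable in both cohorts.
#'
#' @param alpha_total family-wise level (default 0.05).
#' @param normality_alpha level of any normality gates (default 0.05).
#' @return object of class `comparison_config`.
#' @export
comparison_config <- function(alpha_total = 0.05, normality_alpha = 0.05) {
  structure(list(alpha_total = alpha_total,
                 normality_alpha = normality_alpha),
            class = "comparison_config")
}

#' Replication of compositions across cohorts
#'
#' For every PC sum present in both cohorts, checks whether the same
#' constituent is identified as the main constituent (reported for sums with
#' at least two measured constituents in both cohorts) and tests whether the
#' distribution of the reference cohort's main-constituent ratio differs
#' between the cohorts (Kruskal–Wallis), at the Bonferroni-corrected level
#' `alpha_total / n_tests` where `n_tests` is the number of sums testable in
#' both cohorts.
#'
#' @param composition_a,composition_b [summarize_composition()] results for
#'   the reference cohort (a) and the replication cohort (b).
#' @param ratio_sets_a,ratio_sets_b the matching [compute_ratio_set()]
#'   outputs.
#' @param config a [comparison_config()].
#' @return a data frame of class `cohort_comparison`, one row per testable
#'   sum: main constituents, agreement flag, Kruskal–Wallis statistic and
#'   p-value, significance at the Bonferroni level; `alpha` and `n_tests` are
#'   attached as attributes.
#' @export
compare_cohorts <- function(composition_a, ratio_sets_a,
                            composition_b, ratio_sets_b,
                            config = comparison_config()) {
  stopifnot(inherits(composition_a, "sum_composition"),
            inherits(composition_b, "sum_composition"))
  sums_a <- unique(composition_a$sum_label)
  sums_b <- unique(composition_b$sum_label)
  testable <- intersect(sums_a, sums_b)
  abort_if(length(testable) == 0, "no PC sum is present in both cohorts")
  n_tests <- length(testable)
  alpha <- config$alpha_total / n_tests

  rows <- lapply(testable, function(s) {
    ca <- composition_a[composition_a$sum_label == s, , drop = FALSE]
    cb <- composition_b[composition_b$sum_label == s, , drop = FALSE]
    main_a <- ca$constituent[ca$is_main]
    main_b <- cb$constituent[cb$is_main]
    agreement <- if (nrow(ca) >= 2 && nrow(cb) >= 2) {
      identical(main_a, main_b)
    } else NA
    qa <- ratio_sets_a$q[ratio_sets_a$sum_label == s &
                           ratio_sets_a$constituent == main_a]
    qb <- ratio_sets_b$q[ratio_sets_b$sum_label == s &
                           ratio_sets_b$constituent == main_a]
    if (length(qa) >= 2 && length(qb) >= 2 &&
        stats::sd(c(qa, qb)) > 0) {
      kw <- stats::kruskal.test(list(qa, qb))
      stat <- unname(kw$statistic); p <- kw$p.value
    } else {
      stat <- NA_real_; p <- NA_real_
    }
    data.frame(sum_label = s, main_a = main_a,
               main_b = if (length(main_b)) main_b else NA_character_,
               agreement = agreement,
               n_constituents_a = nrow(ca), n_constituents_b = nrow(cb),
               statistic = stat, p_value = p,
               significant = !is.na(p) & p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "n_tests") <- n_tests
  class(out) <- c("cohort_comparison", "data.frame")
  out
}
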