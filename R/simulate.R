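#' Default multi-timepoint (challenge) sampling design
#'
#' A HuMet-style design: `n_timepoints` timepoints per subject, six of which
#' are designated baseline/intervention pairs of the three lipid-related
#' challenges (extended fasting, physical activity, oral lipid tolerance).
#'
#' @param n_timepoints number of timepoints per subject (default 56).
#' @return data frame with columns `timepoint`, `challenge`, `phase`.
#' @export
challenge_timepoints <- function(n_timepoints = 56L) {
  abort_if(n_timepoints < 6L, "need at least 6 timepoints for 3 challenges")
  tp <- data.frame(timepoint = sprintf("t%02d", seq_len(n_timepoints)),
                   challenge = NA_character_, phase = NA_character_,
                   stringsAsFactors = FALSE)
  marks <- data.frame(
    challenge = rep(c("FASTING", "PAT", "OLTT"), each = 2),
    phase = rep(c("baseline", "intervention"), 3))
  idx <- round(seq(1L, n_timepoints, length.out = 6L))
  tp$challenge[idx] <- marks$challenge
  tp$phase[idx] <- marks$phase
  tp
}

#' Default simulated PC sum panel
#'
#' Three PC sums with constituent structures spanning the cases seen in real
#' plasma: one dominant constituent plus minor ones, two co-dominant
#' constituents, and a single measured constituent; each with an unmeasured
#' remainder. Base concentrations are in the μmol/L range typical of
#' abundant plasma PCs.
#'
#' @return list of per-sum specifications (sum_label, constituents,
#'   proportions, remainder_fraction, base_conc).
#' @export
default_sum_panel <- function() {
  list(
    list(sum_label = "PC aa C36:2",
         constituents = c("PC 16:0_20:2", "PC 18:0_18:2", "PC 18:1_18:1"),
         proportions = c(0.04, 0.76, 0.10), remainder_fraction = 0.10,
         base_conc = 40),
    list(sum_label = "PC aa C34:3",
         constituents = c("PC 14:0_20:3", "PC 16:0_18:3", "PC 18:2_16:1"),
         proportions = c(0.05, 0.45, 0.40), remainder_fraction = 0.10,
         base_conc = 10),
    list(sum_label = "PC aa C32:2",
         constituents = "PC 14:0_18:2",
         proportions = 0.85, remainder_fraction = 0.15,
         base_conc = 4))
}

#' Synthetic paired-cohort configuration
#'
#' Ground-truth configuration for [simulate_paired_cohort()]. Per-sum true
#' constituent proportions `p_ij` plus the remainder fraction must sum to 1.
#' Platform efficiency factors scale what each platform reports relative to
#' the latent concentration (values differing from 1 emulate extraction/
#' ionization efficiency differences between the methods and can push
#' estimated proportions above 1). Biological variability is log-normal with
#' additive subject and timepoint effects on the log scale; measurement
#' noise is multiplicative log-normal with the stated CV per platform.
#'
#' @param n_subjects number of subjects (default 4).
#' @param timepoints design data frame as from [challenge_timepoints()].
#' @param sums per-sum specification list as in [default_sum_panel()].
#' @param efficiency_species species-level platform efficiency: scalar or
#'   named per-sum-label vector.
#' @param efficiency_fa fatty-acid-level platform efficiency: scalar or named
#'   per-constituent vector.
#' @param sd_between between-subject SD of log-concentration (default 0.3).
#' @param sd_within within-subject (timepoint) SD of log-concentration
#'   (default 0.2).
#' @param cv_species,cv_fa measurement coefficient of variation per platform
#'   (default 0.1 each).
#' @param challenge_effect optional additive log-scale shift applied to
#'   intervention timepoints (default 0; exercise for the paired tests).
#' @param missing_rate probability that an observed value is set missing
#'   (default 0).
#' @param seed integer seed governing all randomness.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 4L,
                             timepoints = challenge_timepoints(),
                             sums = default_sum_panel(),
                             efficiency_species = 1, efficiency_fa = 1,
                             sd_between = 0.3, sd_within = 0.2,
                             cv_species = 0.1, cv_fa = 0.1,
                             challenge_effect = 0, missing_rate = 0,
                             seed = 1L) {
  abort_if(n_subjects < 1, "need at least one subject")
  abort_if(cv_species < 0 || cv_fa < 0, "CVs must be >= 0")
  abort_if(missing_rate < 0 || missing_rate >= 1,
           "missing_rate must be in [0, 1)")
  sums <- lapply(sums, function(s) {
    abort_if(any(s$proportions < 0) || s$remainder_fraction < 0,
             "proportions must be >= 0 for %s", s$sum_label)
    abort_if(length(s$proportions) != length(s$constituents),
             "one proportion per constituent required for %s", s$sum_label)
    abort_if(abs(sum(s$proportions) + s$remainder_fraction - 1) > 1e-8,
             "proportions + remainder must sum to 1 for %s (got %.6f)",
             s$sum_label, sum(s$proportions) + s$remainder_fraction)
    # store canonical labels so simulated analytes match catalog output
    s$sum_label <- format_lipid_name(parse_lipid_name(s$sum_label), "kit")
    s$constituents <- vapply(s$constituents, function(l) {
      format_lipid_name(parse_lipid_name(l), "fatty_acid")
    }, character(1), USE.NAMES = FALSE)
    s
  })
  structure(list(n_subjects = as.integer(n_subjects), timepoints = timepoints,
                 sums = sums, efficiency_species = efficiency_species,
                 efficiency_fa = efficiency_fa, sd_between = sd_between,
                 sd_within = sd_within, cv_species = cv_species,
                 cv_fa = cv_fa, challenge_effect = challenge_effect,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "synthetic_config")
}

# look up a possibly-named efficiency vector
efficiency_for <- function(eff, label) {
  if (is.null(names(eff))) return(unname(eff[1]))
  if (label %in% names(eff)) return(unname(eff[[label]]))
  1
}

# multiplicative log-normal noise with mean 1 and the given CV
ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

#' Simulate a paired-platform cohort with known ground truth
#'
#' Draws latent per-sample PC sum concentrations log-normally with subject
#' and timepoint effects; splits them into constituents according to the
#' configured true proportions (the remainder fraction models constituents
#' not measured on the side-chain resolving platform); and observes the sum
#' on the species-level platform and each constituent on the fatty-acid-level
#' platform, each scaled by its platform efficiency and multiplied by
#' log-normal measurement noise. The expected estimable ratio for each pair,
#' E[q_ij] = (eff_j / eff_i) * p_ij * exp(sigma_i^2) with sigma_i the
#' species-platform log-noise SD, is returned as ground truth (the last
#' factor is the mean of the reciprocal denominator noise).
#'
#' @param config a [synthetic_config()].
#' @return list with `species` and `fa` ([concentration_matrix()] objects)
#'   and `truth` (list: `expected_q` data frame, `latent_sums` matrix,
#'   `config`).
#' @examples
#' sim <- simulate_paired_cohort(synthetic_config(seed = 7))
#' dim(sim$species)
#' @export
simulate_paired_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_preserved_seed(config$seed, {
    tp <- config$timepoints
    samples <- expand.grid(subject = sprintf("sub%02d",
                                             seq_len(config$n_subjects)),
                           timepoint = tp$timepoint,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    samples <- samples[order(samples$subject, samples$timepoint), ,
                       drop = FALSE]
    samples$challenge <- tp$challenge[match(samples$timepoint, tp$timepoint)]
    samples$phase <- tp$phase[match(samples$timepoint, tp$timepoint)]
    samples$cohort <- "synthetic"
    samples$sample_id <- paste0(samples$subject, "_", samples$timepoint)
    n <- nrow(samples)

    sum_labels <- vapply(config$sums, `[[`, character(1), "sum_label")
    all_constituents <- unlist(lapply(config$sums, `[[`, "constituents"))
    abort_if(anyDuplicated(all_constituents) > 0,
             "constituents must be unique across sums")

    species <- matrix(NA_real_, n, length(sum_labels),
                      dimnames = list(samples$sample_id, sum_labels))
    fa <- matrix(NA_real_, n, length(all_constituents),
                 dimnames = list(samples$sample_id, all_constituents))
    latent <- matrix(NA_real_, n, length(sum_labels),
                     dimnames = list(samples$sample_id, sum_labels))

    intervention <- !is.na(samples$phase) & samples$phase == "intervention"
    truth_rows <- list()
    sigma_i <- sqrt(log(1 + config$cv_species^2))
    for (k in seq_along(config$sums)) {
      s <- config$sums[[k]]
      subj_eff <- stats::rnorm(config$n_subjects, 0, config$sd_between)
      names(subj_eff) <- sprintf("sub%02d", seq_len(config$n_subjects))
      log_latent <- log(s$base_conc) + subj_eff[samples$subject] +
        stats::rnorm(n, 0, config$sd_within) +
        config$challenge_effect * intervention
      latent[, k] <- exp(log_latent)

      eff_i <- efficiency_for(config$efficiency_species, s$sum_label)
      species[, k] <- eff_i * latent[, k] * ln_noise(n, config$cv_species)
      for (j in seq_along(s$constituents)) {
        eff_j <- efficiency_for(config$efficiency_fa, s$constituents[j])
        fa[, s$constituents[j]] <- eff_j * s$proportions[j] * latent[, k] *
          ln_noise(n, config$cv_fa)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          sum_label = s$sum_label, constituent = s$constituents[j],
          p_true = s$proportions[j],
          expected_q = eff_j / eff_i * s$proportions[j] * exp(sigma_i^2),
          remainder_fraction = s$remainder_fraction,
          stringsAsFactors = FALSE)
      }
    }
    if (config$missing_rate > 0) {
      species[stats::runif(length(species)) < config$missing_rate] <- NA
      fa[stats::runif(length(fa)) < config$missing_rate] <- NA
    }
    meta_cols <- c("sample_id", "subject", "timepoint", "challenge", "phase",
                   "cohort")
    truth <- do.call(rbind, truth_rows)
    rownames(truth) <- NULL
    list(
      species = concentration_matrix(species, samples[meta_cols],
                                     "species_level_kit"),
      fa = concentration_matrix(fa, samples[meta_cols], "fatty_acid_level"),
      truth = list(expected_q = truth, latent_sums = latent, config = config))
  })
}

#' Write a simulated cohort to delimited text
#'
#' Writes the species-level and fatty-acid-level tables in the schema read by
#' [read_concentration_table()] (metadata columns then analyte columns), and
#' the ground-truth expected ratios as a third TSV.
#'
#' @param sim result of [simulate_paired_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_simulated_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_one <- function(mat, file) {
    df <- cbind(mat$samples, as.data.frame(mat$values))
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    file
  }
  p1 <- write_one(sim$species, file.path(dir, "species_level.tsv"))
  p2 <- write_one(sim$fa, file.path(dir, "fatty_acid_level.tsv"))
  p3 <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth$expected_q, p3, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2, p3))
}
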