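test_that("ratios are elementwise with missing/zero denominators excluded", {
  cats <- assemble_constituent_catalog(
    "PC aa C36:2", measured_analytes = c("PC 18:0_18:2", "PC 18:1_18:1"))
  tm <- toy_matrices("PC aa C36:2", c(2, 4, 6, NA, 0),
                     list(`PC 18:0_18:2` = c(1, 2, 3, 5, 5),
                          `PC 18:1_18:1` = c(0.5, NA, 1.5, 1, 1)))
  rs <- compute_ratio_set(tm$species, tm$fa, cats)
  a <- rs[rs$constituent == "PC 18:0_18:2", ]
  expect_equal(a$q, c(0.5, 0.5, 0.5))          # elementwise oracle
  expect_equal(a$sample_id, c("s01", "s02", "s03"))  # NA and 0 denom dropped
  b <- rs[rs$constituent == "PC 18:1_18:1", ]
  expect_equal(b$sample_id, c("s01", "s03"))   # missing numerator dropped
  expect_equal(b$q, c(0.25, 0.25))
})

test_that("ratios are invariant under common rescaling of both platforms", {
  cats <- panel_catalogs()
  sim <- simulate_paired_cohort(synthetic_config(seed = 5))
  rs <- compute_ratio_set(sim$species, sim$fa, cats)
  for (c_scale in c(0.2, 7)) {
    sp <- sim$species; sp$values <- sp$values * c_scale
    fa <- sim$fa; fa$values <- fa$values * c_scale
    rs2 <- compute_ratio_set(sp, fa, cats)
    expect_equal(rs2$q, rs$q)
  }
})

test_that("composition summaries compute means, percentiles and categories", {
  cats <- assemble_constituent_catalog("PC aa C36:2",
                                       measured_analytes = "PC 18:0_18:2")
  tm <- toy_matrices("PC aa C36:2", rep(1, 5),
                     list(`PC 18:0_18:2` = rep(0.4, 5)))
  comp <- summarize_composition(compute_ratio_set(tm$species, tm$fa, cats))
  expect_equal(comp$mean_q, 0.4)
  expect_equal(comp$ci5, 0.4)
  expect_equal(comp$ci95, 0.4)
  expect_equal(comp$category, "I")
  expect_equal(comp$sum_of_proportions, 0.4)
  expect_true(comp$is_main)

  # percentiles use linear interpolation between order statistics
  tm2 <- toy_matrices("PC aa C36:2", rep(1, 21),
                      list(`PC 18:0_18:2` = seq(0, 1, length.out = 21)))
  comp2 <- summarize_composition(compute_ratio_set(tm2$species, tm2$fa, cats))
  expect_equal(comp2$ci5, stats::quantile(seq(0, 1, length.out = 21), 0.05,
                                          names = FALSE))
  expect_equal(comp2$mean_q, 0.5)
})

test_that("category thresholds are strict step functions at 0.2 and 0.8", {
  cats <- assemble_constituent_catalog("PC aa C36:2",
                                       measured_analytes = "PC 18:0_18:2")
  for (case in list(list(q = 0.2, cat = "none"),
                    list(q = 0.2000001, cat = "I"),
                    list(q = 0.8, cat = "I"),
                    list(q = 0.8000001, cat = "II"),
                    list(q = 0.9670, cat = "II"),
                    list(q = 0.3584, cat = "I"),
                    list(q = 0.0820, cat = "none"))) {
    tm <- toy_matrices("PC aa C36:2", rep(1, 3),
                       list(`PC 18:0_18:2` = rep(case$q, 3)))
    comp <- summarize_composition(compute_ratio_set(tm$species, tm$fa, cats))
    expect_equal(comp$category, case$cat, label = sprintf("q=%g", case$q))
  }
})

test_that("mean ratio estimates lie within the observed ratio range", {
  cats <- panel_catalogs()
  sim <- simulate_paired_cohort(synthetic_config(seed = 23))
  rs <- compute_ratio_set(sim$species, sim$fa, cats)
  comp <- summarize_composition(rs)
  for (i in seq_len(nrow(comp))) {
    qs <- rs$q[rs$sum_label == comp$sum_label[i] &
                 rs$constituent == comp$constituent[i]]
    expect_gte(comp$mean_q[i], min(qs))
    expect_lte(comp$mean_q[i], max(qs))
  }
  # sum of proportions is the exact sum of member means
  for (s in unique(comp$sum_label)) {
    idx <- comp$sum_label == s
    expect_equal(unique(comp$sum_of_proportions[idx]),
                 sum(comp$mean_q[idx]))
  }
})

test_that("main constituent is the largest mean with deterministic ties", {
  cats <- assemble_constituent_catalog(
    "PC aa C36:2", measured_analytes = c("PC 18:0_18:2", "PC 18:1_18:1"))
  tm <- toy_matrices("PC aa C36:2", rep(1, 4),
                     list(`PC 18:0_18:2` = rep(0.5, 4),
                          `PC 18:1_18:1` = rep(0.5, 4)))
  comp <- summarize_composition(compute_ratio_set(tm$species, tm$fa, cats))
  expect_equal(comp$constituent[comp$is_main], "PC 18:0_18:2")
  expect_equal(sum(comp$is_main), 1L)
})

test_that("sample filters restrict the composition estimate", {
  cats <- assemble_constituent_catalog("PC aa C36:2",
                                       measured_analytes = "PC 18:0_18:2")
  tm <- toy_matrices("PC aa C36:2", rep(1, 4),
                     list(`PC 18:0_18:2` = c(0.1, 0.1, 0.9, 0.9)))
  rs <- compute_ratio_set(tm$species, tm$fa, cats)
  comp_a <- summarize_composition(rs, sample_filter = c("s01", "s02"))
  expect_equal(comp_a$mean_q, 0.1)
  comp_b <- summarize_composition(rs, function(d) d$subject == "A")
  expect_equal(comp_b$n_used, 2L)
})

test_that("within-platform fractions sum to one and flag partial samples", {
  cats <- assemble_constituent_catalog(
    "PC aa C36:2",
    measured_analytes = c("PC 16:0_20:2", "PC 18:0_18:2", "PC 18:1_18:1"))
  tm <- toy_matrices("PC aa C36:2", rep(1, 3),
                     list(`PC 16:0_20:2` = c(1, 1, 0),
                          `PC 18:0_18:2` = c(1, NA, 0),
                          `PC 18:1_18:1` = c(2, 1, 0)))
  fr <- lipidyzer_fractions(tm$fa, cats)
  s1 <- fr[fr$sample_id == "s01", ]
  expect_equal(s1$fraction[match(c("PC 16:0_20:2", "PC 18:0_18:2",
                                   "PC 18:1_18:1"), s1$constituent)],
               c(0.25, 0.25, 0.5))
  expect_false(any(s1$partial))
  s2 <- fr[fr$sample_id == "s02", ]
  expect_true(all(s2$partial))
  expect_equal(sum(s2$fraction, na.rm = TRUE), 1)  # over remaining members
  s3 <- fr[fr$sample_id == "s03", ]
  expect_true(all(is.na(s3$fraction)))             # all-zero denominator

  # single measured constituent: fraction 1 wherever observed
  cats1 <- assemble_constituent_catalog("PC aa C32:2",
                                        measured_analytes = "PC 14:0_18:2")
  tm1 <- toy_matrices("PC aa C32:2", rep(1, 3),
                      list(`PC 14:0_18:2` = c(2, 5, NA)))
  fr1 <- lipidyzer_fractions(tm1$fa, cats1)
  expect_equal(fr1$fraction, c(1, 1, NA))
})
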