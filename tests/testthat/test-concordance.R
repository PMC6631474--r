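single_catalog <- function() {
  assemble_constituent_catalog(
    "PC aa C36:2",
    measured_analytes = c("PC 18:0_18:2", "PC 18:1_18:1"))[[1]]
}

test_that("exact proportional data yield the true slope and R^2 = 1", {
  x1 <- c(1, 2, 3, 4, 5); x2 <- c(0.5, 1, 1.5, 2, 2.5)
  tm <- toy_matrices("PC aa C36:2", 2 * (x1 + x2),
                     list(`PC 18:0_18:2` = x1, `PC 18:1_18:1` = x2))
  fit <- fit_proportional_model(tm$species, tm$fa, single_catalog())
  expect_equal(fit$b, 2)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n, 5L)
})

test_that("R^2 matches the closed-form variance ratio for orthogonal noise", {
  # residuals orthogonal to the predictor and centred: for y = b*x + e,
  # centred R^2 = b^2 * Sxx / (b^2 * Sxx + See)
  x <- c(1, 2, 3, 4, 5, 6)
  e <- c(1, -1, -1, 1, 1, -1) * 0.3
  e <- e - mean(e)
  e <- e - sum(e * (x - mean(x))) / sum((x - mean(x))^2) * (x - mean(x))
  b <- 1.5
  y <- b * x + e
  tm <- toy_matrices("PC aa C36:2", y,
                     list(`PC 18:0_18:2` = x * 0.7, `PC 18:1_18:1` = x * 0.3))
  fit <- fit_proportional_model(tm$species, tm$fa, single_catalog())
  sxx <- sum((x - mean(x))^2); see <- sum(e^2)
  expect_equal(fit$r_squared, b^2 * sxx / (b^2 * sxx + see),
               tolerance = 1e-10)
  # and the centred definition agrees with lm()'s R^2 on the same data
  lm_r2 <- summary(stats::lm(y ~ x))$r.squared
  expect_equal(fit$r_squared, lm_r2, tolerance = 1e-10)
  # the no-intercept slope matches lm(y ~ x + 0)
  lm_b <- unname(stats::coef(stats::lm(y ~ x + 0)))
  expect_equal(fit$b, lm_b, tolerance = 1e-10)
})

test_that("uncorrelated predictor gives near-zero centred R^2 at large n", {
  set.seed(47)
  n <- 2000
  x <- stats::rlnorm(n)
  y <- stats::rlnorm(n)
  tm <- toy_matrices("PC aa C36:2", y,
                     list(`PC 18:0_18:2` = x / 2, `PC 18:1_18:1` = x / 2))
  fit <- fit_proportional_model(tm$species, tm$fa, single_catalog())
  expect_lt(fit$r_squared, 0.01)
  # the uncentred no-intercept variant would be misleadingly large here
  fit_u <- fit_proportional_model(tm$species, tm$fa, single_catalog(),
                                  r_squared = "uncentered")
  expect_gt(fit_u$r_squared, fit$r_squared)
})

test_that("slope is scale-equivariant in the constituents", {
  set.seed(53)
  x <- stats::rlnorm(20); y <- 1.3 * x * exp(stats::rnorm(20, 0, 0.05))
  for (c_scale in c(0.25, 4)) {
    tm <- toy_matrices("PC aa C36:2", y,
                       list(`PC 18:0_18:2` = x / 2, `PC 18:1_18:1` = x / 2))
    fit <- fit_proportional_model(tm$species, tm$fa, single_catalog())
    tm2 <- toy_matrices("PC aa C36:2", y,
                        list(`PC 18:0_18:2` = c_scale * x / 2,
                             `PC 18:1_18:1` = c_scale * x / 2))
    fit2 <- fit_proportional_model(tm2$species, tm2$fa, single_catalog())
    expect_equal(fit2$b, fit$b / c_scale, tolerance = 1e-12)
    expect_equal(fit2$r_squared, fit$r_squared, tolerance = 1e-12)
  }
})

test_that("degenerate concordance inputs are rejected", {
  tm <- toy_matrices("PC aa C36:2", c(1, 2, 3),
                     list(`PC 18:0_18:2` = c(1, 1, 1),
                          `PC 18:1_18:1` = c(1, 1, 1)))
  expect_error(fit_proportional_model(tm$species, tm$fa, single_catalog()),
               "zero-variance")
  tm2 <- toy_matrices("PC aa C36:2", c(1, 2),
                      list(`PC 18:0_18:2` = c(1, 2),
                           `PC 18:1_18:1` = c(1, 2)))
  expect_error(fit_proportional_model(tm2$species, tm2$fa, single_catalog()),
               "fewer than 3")
  # the per-sum report records the problem instead of failing
  cats <- assemble_constituent_catalog(
    "PC aa C36:2", measured_analytes = c("PC 18:0_18:2", "PC 18:1_18:1"))
  rep <- concordance_report(tm$species, tm$fa, cats)
  expect_true(is.na(rep$b))
  expect_match(rep$note, "zero-variance")
  rep2 <- concordance_report(tm2$species, tm2$fa, cats)
  expect_match(rep2$note, "fewer than 3")
})

test_that("Bland-Altman differences, means and classification are exact", {
  # identical series: all differences zero
  x <- c(1, 2, 3, 4)
  tm <- toy_matrices("PC aa C36:2", x,
                     list(`PC 18:0_18:2` = x / 2, `PC 18:1_18:1` = x / 2))
  ba <- bland_altman_stats(tm$species, tm$fa, single_catalog())
  expect_equal(ba$difference, rep(0, 4))
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$classification, "within_1SD")

  # constituents uniformly 10% above the sum: negative mean difference
  tm <- toy_matrices("PC aa C36:2", x,
                     list(`PC 18:0_18:2` = 1.1 * x / 2,
                          `PC 18:1_18:1` = 1.1 * x / 2))
  ba <- bland_altman_stats(tm$species, tm$fa, single_catalog())
  expect_lt(ba$mean_difference, 0)
  expect_equal(ba$mean, (x + 1.1 * x) / 2)
  # mean difference equals the difference of means exactly
  expect_equal(ba$mean_difference, mean(x) - mean(1.1 * x))

  # constructed mean difference of 1.5 reference SDs: within 2 SD, not 1 SD
  y <- c(10, 11, 12, 13, 14)
  shift <- 1.5 * stats::sd(y)
  tm <- toy_matrices("PC aa C36:2", y,
                     list(`PC 18:0_18:2` = (y - shift) / 2,
                          `PC 18:1_18:1` = (y - shift) / 2))
  ba <- bland_altman_stats(tm$species, tm$fa, single_catalog())
  expect_equal(ba$mean_difference, shift)
  expect_equal(ba$classification, "within_2SD")
})

test_that("complete-case rule never cumulates a partial constituent sum", {
  tm <- toy_matrices("PC aa C36:2", c(2, 2, 2, 2),
                     list(`PC 18:0_18:2` = c(1, NA, 1, 1),
                          `PC 18:1_18:1` = c(1, 1, NA, 1)))
  ba <- bland_altman_stats(tm$species, tm$fa, single_catalog())
  expect_equal(ba$n, 2L)
  expect_equal(ba$sample_id, c("s01", "s04"))
})
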