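make_pairs <- function(n, slope = 0.9, noise_sd = 0.1, n_strains = 11,
                       strain_offsets = rep(0, n_strains), seed = 1) {
  set.seed(seed)
  strain <- sprintf("S%02d", sample.int(n_strains, n, replace = TRUE))
  manual <- runif(n, -0.4, 0.4)
  auto <- slope * manual + strain_offsets[as.integer(substring(strain, 2))] +
    rnorm(n, sd = noise_sd)
  data.frame(strain = strain, compound = "iaa",
             manual_ci = manual, automated_ci = pmax(-1, pmin(1, auto)),
             stringsAsFactors = FALSE)
}

test_that("perfect agreement gives slope 1, intercept 0, R^2 = 1", {
  d <- data.frame(manual_ci = c(-0.5, -0.1, 0.2, 0.6, 0.9))
  d$automated_ci <- d$manual_ci
  f <- fit_agreement(d)
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)
  expect_equal(f$r_squared, 1)
  expect_identical(f$n, 5L)
})

test_that("a constant automated CI has no explanatory power", {
  d <- data.frame(manual_ci = c(-0.5, 0, 0.5, 0.8),
                  automated_ci = rep(0.2, 4))
  expect_equal(fit_agreement(d)$r_squared, 0)
})

test_that("degenerate and undersized inputs are rejected", {
  expect_error(fit_agreement(data.frame(manual_ci = c(0.1, 0.2),
                                        automated_ci = c(0.1, 0.2))),
               "at least 3")
  expect_error(fit_agreement(data.frame(manual_ci = rep(0.3, 5),
                                        automated_ci = runif(5))),
               "zero variance")
  expect_error(fit_agreement(data.frame(manual_ci = c(0, 2, 0.5),
                                        automated_ci = c(0, 0.5, 0.5))),
               "outside")
})

test_that("simulated agreement recovers the known slope and analytic R^2", {
  d <- make_pairs(200, slope = 0.9, noise_sd = 0.1, seed = 7)
  f <- fit_agreement(d)
  var_manual <- 0.8^2 / 12                 # variance of U(-0.4, 0.4)
  r2_expected <- (0.9^2 * var_manual) / (0.9^2 * var_manual + 0.1^2)
  expect_equal(f$slope, 0.9, tolerance = 0.05 / 0.9)
  expect_lt(abs(f$r_squared - r2_expected), 0.05)
  # R^2 equals the squared Pearson correlation
  expect_equal(f$r_squared, cor(d$manual_ci, d$automated_ci)^2,
               tolerance = 1e-10)
})

test_that("the reference strain estimate is exactly zero", {
  d <- make_pairs(150, seed = 3)
  res <- strain_effect_anova(d)
  expect_identical(res$estimates$estimate[res$estimates$strain ==
                                            res$reference], 0)
  expect_identical(res$df1, length(unique(d$strain)) - 1L)
  expect_gte(res$p_value, 0); expect_lte(res$p_value, 1)
})

test_that("a real strain offset is detected with its CI excluding zero", {
  offs <- rep(0, 11); offs[4] <- 0.5
  d <- make_pairs(220, strain_offsets = offs, noise_sd = 0.1, seed = 11)
  res <- strain_effect_anova(d)
  est <- res$estimates[res$estimates$strain == "S04", ]
  expect_gt(est$lwr, 0)
  expect_lt(res$p_value, 0.01)
})

test_that("aliased strain terms raise a rank-deficiency error", {
  d <- data.frame(strain = rep(c("A", "B"), each = 4),
                  manual_ci = rep(c(0, 0.5), each = 4),
                  automated_ci = rnorm(8, sd = 0.1))
  expect_error(strain_effect_anova(d), "rank-deficient")
})

test_that("strain ANOVA rejects designs it cannot support", {
  d <- make_pairs(30, seed = 5)
  expect_error(strain_effect_anova(d[d$strain == d$strain[1], ]),
               "at least 2 strains")
})

test_that("heritability is 0-ish under the null and 1 in the noiseless limit", {
  h2s <- vapply(1:100, function(s) {
    set.seed(s)
    d <- data.frame(strain = rep(sprintf("S%02d", 1:11), each = 9),
                    value = rnorm(99))
    broad_sense_heritability(d)$h2
  }, numeric(1))
  expect_lte(mean(h2s), 0.05)

  d <- data.frame(strain = rep(c("A", "B", "C"), each = 3),
                  value = rep(c(0.1, 0.5, 0.9), each = 3))
  h <- broad_sense_heritability(d)
  expect_equal(h$h2, 1)
  expect_equal(h$var_residual, 0)
})

test_that("heritability is invariant to shift and positive rescaling", {
  set.seed(9)
  d <- data.frame(strain = rep(LETTERS[1:6], each = 8),
                  value = rnorm(48) + rep(rnorm(6), each = 8))
  h0 <- broad_sense_heritability(d)$h2
  d2 <- d; d2$value <- 3.7 * d$value + 12
  expect_equal(broad_sense_heritability(d2)$h2, h0, tolerance = 1e-12)
})

test_that("moment and REML variance components agree on balanced data", {
  skip_if_not_installed("lme4")
  set.seed(21)
  d <- data.frame(strain = rep(sprintf("S%02d", 1:11), each = 9))
  d$value <- rep(rnorm(11), each = 9) + rnorm(99)
  mom <- broad_sense_heritability(d, method = "anova")
  reml <- broad_sense_heritability(d, method = "reml")
  expect_equal(mom$h2, reml$h2, tolerance = 0.05)
  expect_identical(mom$method, "anova")
  expect_identical(reml$method, "reml")
})

test_that("heritability is an error, not 1, for a single strain", {
  d <- data.frame(strain = rep("N2", 9), value = rnorm(9))
  expect_error(broad_sense_heritability(d), "single strain")
})
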