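test_that("a noiseless power law is fitted exactly", {
  v <- 10^seq(-3, 1, length.out = 5)
  ds <- as_calibration_dataset(data.frame(
    species = paste0("s", 1:5), group = "synthetic",
    vol_CH_m3 = v, M_b_kg = 100 * v))
  f <- suppressWarnings(fit_ols_loglog(ds))  # exact fit trips summary.lm
  expect_equal(f$a, 2, tolerance = 1e-12)
  expect_equal(f$b, 1, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$mse, 0, tolerance = 1e-20)
  pe <- percent_prediction_error(ds, f)
  expect_equal(pe$mean_PE, 0, tolerance = 1e-9)
})

test_that("fit preconditions are enforced", {
  ds <- generate_allometric_dataset(3, 1, 0.1, n = 10, seed = 1)
  expect_error(fit_ols_loglog(ds[1:2, ]), "at least 3")
  flat <- as.data.frame(ds)
  flat$vol_CH_m3 <- 0.5
  expect_error(fit_ols_loglog(as_calibration_dataset(flat)), "singular design")
})

test_that("volume rescaling shifts the intercept by -b*log10(k) and nothing else", {
  ds <- generate_allometric_dataset(3.1, 0.95, 0.05, n = 20, seed = 42)
  f0 <- fit_ols_loglog(ds)
  k <- 137.5
  ds2 <- as.data.frame(ds)
  ds2$vol_CH_m3 <- ds2$vol_CH_m3 * k
  f1 <- fit_ols_loglog(as_calibration_dataset(ds2))
  expect_equal(f1$a, f0$a - f0$b * log10(k), tolerance = 1e-10)
  expect_equal(f1$b, f0$b, tolerance = 1e-10)
  expect_equal(f1$r2, f0$r2, tolerance = 1e-10)
  expect_equal(f1$mse, f0$mse, tolerance = 1e-10)
  # %PE is scale-free too
  expect_equal(percent_prediction_error(ds, f0)$mean_PE,
               percent_prediction_error(as_calibration_dataset(ds2), f1)$mean_PE,
               tolerance = 1e-8)
})

test_that("OLS recovers generator parameters without bias, with honest CIs", {
  a_true <- 3.0; b_true <- 1.0; sigma <- 0.07
  fits <- lapply(1:500, function(s)
    fit_ols_loglog(generate_allometric_dataset(a_true, b_true, sigma, n = 30,
                                               seed = s)))
  a_hat <- vapply(fits, `[[`, 0, "a")
  b_hat <- vapply(fits, `[[`, 0, "b")
  expect_lt(abs(mean(a_hat) - a_true), 0.02)
  expect_lt(abs(mean(b_hat) - b_true), 0.02)
  cover_a <- mean(vapply(fits, function(f)
    f$ci_a[1] <= a_true && a_true <= f$ci_a[2], TRUE))
  cover_b <- mean(vapply(fits, function(f)
    f$ci_b[1] <= b_true && b_true <= f$ci_b[2], TRUE))
  expect_gte(cover_a, 0.93); expect_lte(cover_a, 0.97)
  expect_gte(cover_b, 0.93); expect_lte(cover_b, 0.97)
})

test_that("correction factor follows the base-10 smearing formula", {
  expect_equal(correction_factor(0), 1)
  expect_equal(correction_factor(0.0052), 1.0138804, tolerance = 1e-6)
  expect_equal(correction_factor(0.013), 1.0350630, tolerance = 1e-6)
  expect_error(correction_factor(-0.1), ">= 0")
  # monotone in MSE
  mse <- seq(0, 0.05, length.out = 20)
  expect_true(all(diff(correction_factor(mse)) > 0))
})

test_that("mass prediction back-transforms, corrects, and flags extrapolation", {
  fit <- fit_ols_loglog(generate_allometric_dataset(3.13, 1.011, 0.06, n = 25,
                                                    seed = 3,
                                                    vol_range = c(5e-4, 3)))
  eq <- predictive_equation(fit, "combined mammal")
  # identity-transform equation: a = 0, b = 1 predicts mass = volume
  ident <- fit
  ident$a <- 0; ident$b <- 1; ident$mse <- 0
  p <- suppressWarnings(predict_mass(2, predictive_equation(ident),
                                     apply_cf = FALSE))
  expect_equal(p$mass, 2, tolerance = 1e-12)

  manual <- fit
  manual$a <- 3.13; manual$b <- 1.011; manual$mse <- 0.0052
  p1 <- predict_mass(1, predictive_equation(manual), apply_cf = FALSE)
  expect_equal(p1$mass, 10^3.13, tolerance = 1e-9)
  p2 <- predict_mass(1, predictive_equation(manual), apply_cf = TRUE)
  expect_equal(p2$mass, 10^3.13 * correction_factor(0.0052), tolerance = 1e-9)
  expect_true(p1$lwr < p1$mass && p1$mass < p1$upr)

  expect_warning(predict_mass(100, eq), "extrapolated")
  expect_error(predict_mass(-1, eq), "> 0")
})

test_that("the published bird equation predicts the ostrich mass", {
  fit <- fit_ols_loglog(generate_allometric_dataset(2.70, 0.81, 0.1, n = 20,
                                                    seed = 4,
                                                    vol_range = c(5e-4, 0.2)))
  fit$a <- 2.70; fit$b <- 0.81
  p <- predict_mass(7.17e-2, predictive_equation(fit, "bird"),
                    apply_cf = FALSE)
  expect_equal(p$mass, 59.29, tolerance = 1e-3)
  expect_false(p$extrapolated)
})

test_that("percentage prediction error supports both denominator conventions", {
  ds <- generate_allometric_dataset(3, 1, 0.1, n = 15, seed = 5)
  f <- fit_ols_loglog(ds)
  pred <- 10^(f$a + f$b * log10(ds$vol_CH_m3))
  pe_p <- percent_prediction_error(ds, f, "predicted")
  pe_o <- percent_prediction_error(ds, f, "observed")
  expect_equal(pe_p$mean_PE, mean(100 * abs(ds$M_b_kg - pred) / pred))
  expect_equal(pe_o$mean_PE, mean(100 * abs(ds$M_b_kg - pred) / ds$M_b_kg))
  expect_true(pe_p$ci_PE[1] < pe_p$mean_PE && pe_p$mean_PE < pe_p$ci_PE[2])
  expect_error(percent_prediction_error(ds[1:5, ], f), "rows")
})

test_that("apparent density and its regression behave on constructed data", {
  ds <- as_calibration_dataset(data.frame(
    species = paste0("s", 1:6), group = "synthetic",
    vol_CH_m3 = c(1, 2, 4, 0.5, 0.25, 8),
    M_b_kg = 1000 * c(1, 2, 4, 0.5, 0.25, 8)))
  dens <- apparent_density(ds)
  expect_equal(unname(dens$records$rho_CH), rep(1000, 6))
  expect_equal(unname(dens$group_means["synthetic"]), 1000)
  # constant density: zero slope, zero r2
  reg <- density_mass_regression(dens$records)
  expect_equal(reg$b, 0, tolerance = 1e-9)
  expect_equal(reg$r2, 0, tolerance = 1e-12)
  expect_error(density_mass_regression(dens$records[1:2, ]), "at least 3")
})

test_that("slope ANCOVA holds its type-I error and detects real differences", {
  # null: both groups share the same generating line
  pvals <- vapply(1:1000, function(s) {
    g1 <- generate_allometric_dataset(3, 1, 0.1, n = 10, seed = s,
                                      group = "g1")
    g2 <- generate_allometric_dataset(3, 1, 0.1, n = 10, seed = s + 10000,
                                      group = "g2")
    compare_slopes_ancova(list(g1 = g1, g2 = g2))$p
  }, 0)
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)

  # power: grossly different slopes at tiny noise
  g1 <- generate_allometric_dataset(3, 1.0, 0.01, n = 20, seed = 1, group = "g1")
  g2 <- generate_allometric_dataset(3, 0.5, 0.01, n = 20, seed = 2, group = "g2")
  res <- compare_slopes_ancova(list(g1 = g1, g2 = g2))
  expect_lt(res$p, 1e-6)
  expect_equal(res$df, c(1, 36))
  expect_error(compare_slopes_ancova(list(g1 = g1, g2 = g2[1:2, ])), "n >= 3")
})

test_that("one-way ANOVA separates what it should and only that", {
  x <- rep(c(1, 2, 3), each = 4)
  g <- rep(c("a", "b", "c"), each = 4)
  same <- oneway_anova(rep(x, 2)[1:12], rep(c("a", "b"), 6))
  expect_error(oneway_anova(1:3, c("a", "b", "c")), "n >= 2")
  ident <- oneway_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(ident$F, 0)
  sep <- withr::with_seed(8, oneway_anova(c(rnorm(30), rnorm(30, 5)),
                                          rep(c("a", "b"), each = 30)))
  expect_lt(sep$p, 1e-6)
})

test_that("assumption checks flag heteroscedastic raw fits and pass clean log fits", {
  ds <- generate_allometric_dataset(3, 1, 0.05, n = 50, seed = 10)
  chk <- assumption_checks(ds, "log10")
  expect_gt(chk$shapiro$p, 0.05)
  expect_gt(chk$breusch_pagan$p, 0.05)
  expect_false(chk$recommend_log10)

  # multiplicative noise over three decades of volume is grossly
  # heteroscedastic on the raw scale
  ds2 <- generate_allometric_dataset(3, 1, 0.15, n = 100, seed = 11)
  chk2 <- assumption_checks(ds2, "raw")
  expect_lt(chk2$breusch_pagan$p, 0.05)
  expect_true(chk2$recommend_log10)

  expect_error(assumption_checks(ds[1:3, ]), "at least 4")
})

test_that("paired t-test matches its definition and handles degeneracy", {
  ident <- paired_ttest(1:5, 1:5)
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_error(paired_ttest(1:4, 1:5), "equal length")
  expect_error(paired_ttest(c(1, 2, 3), c(2, 3, 4)), "zero variance")

  # nine specimens, as in the ratite down-sampling comparison
  orig <- withr::with_seed(12, runif(9, 0.01, 0.5))
  down <- orig * 0.995
  noisy_down <- down * withr::with_seed(13, exp(rnorm(9, 0, 0.002)))
  res <- paired_ttest(orig, noisy_down)
  expect_equal(res$df, 8)

  big <- withr::with_seed(14, rnorm(20))
  res2 <- paired_ttest(big + 1 + withr::with_seed(15, rnorm(20, 0, 0.1)), big)
  expect_lt(res2$p, 1e-6)
})
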