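test_that("relative-risk transform matches its closed form", {
  r0 <- rr_from_beta(0, 0.002)
  expect_equal(r0$rr, 1)
  expect_equal(r0$ci_low * r0$ci_high, 1)  # symmetric in log scale about 1
  r <- rr_from_beta(0.001, 0.0005)
  expect_equal(r$rr, 1.01005, tolerance = 5e-6)
  expect_equal(r$ci_low, 1.00020, tolerance = 5e-6)
  expect_equal(r$ci_high, 1.02000, tolerance = 5e-6)
  rz <- rr_from_beta(0.003, 0.001, increment = 0)
  expect_equal(unlist(rz), c(rr = 1, ci_low = 1, ci_high = 1))
  # monotone in beta, widening in se
  expect_gt(rr_from_beta(0.002, 1e-4)$rr, rr_from_beta(0.001, 1e-4)$rr)
  expect_gt(rr_from_beta(0.001, 2e-4)$ci_high, rr_from_beta(0.001, 1e-4)$ci_high)
})

test_that("between-group z-test matches its closed form and is antisymmetric", {
  z <- compare_groups_z(0.003, 0.001, 0.001, 0.001)
  expect_equal(z$z, 1.41421, tolerance = 1e-5)
  expect_equal(z$p, 2 * (1 - pnorm(sqrt(2))), tolerance = 1e-5)
  expect_equal(compare_groups_z(0.5, 0.1, 0.5, 0.2)$z, 0)
  expect_equal(compare_groups_z(0.5, 0.1, 0.5, 0.2)$p, 1)
  sw <- compare_groups_z(0.001, 0.001, 0.003, 0.001)
  expect_equal(sw$z, -z$z)
  expect_equal(sw$p, z$p)
  expect_error(compare_groups_z(1, 0, 2, 0), "zero")
})

test_that("single-lag fits localise the effect at the generating lag", {
  # white-noise exposure, effect only at lag 0
  ex <- simulate_exposure(2100, mean_level = 70, seasonal_amplitude = 0,
                          ar_coef = 0, noise_sd = 15, seed = 71)
  cnt <- simulate_counts(ex, health_sim_config(
    2000, alpha = log(5), beta1 = c(0.0016, 0, 0, 0, 0, 0), seed = 72))
  at0 <- fit_single_lag(cnt, ex, lag = 0, df = 7)
  expect_lt(abs(at0$beta - 0.0016), 3 * at0$se)
  at3 <- fit_single_lag(cnt, ex, lag = 3, df = 7)
  expect_lt(abs(at3$beta), 3 * at3$se)
  expect_equal(at0$rr10, exp(10 * at0$beta))
})

test_that("cumulative distributed-lag fit sums coefficients with full covariance", {
  ex <- simulate_exposure(2100, mean_level = 70, seasonal_amplitude = 0,
                          ar_coef = 0, noise_sd = 15, seed = 81)
  cnt <- simulate_counts(ex, health_sim_config(
    2000, alpha = log(5), beta1 = c(0.0016, 0, 0, 0, 0, 0), seed = 82))
  cum <- fit_cumulative_lag(cnt, ex, max_lag = 5, df = 7)
  expect_lt(abs(cum$beta_sum - 0.0016), 3 * cum$se_sum)
  expect_equal(cum$rr10, exp(10 * cum$beta_sum))
  expect_identical(cum$significant, cum$ci_low > 1 || cum$ci_high < 1)
  # the reported cumulative RR transform: beta_sum = ln(1.016)/10 -> rr10 1.016
  expect_equal(rr_from_beta(log(1.016) / 10, 0.001)$rr, 1.016)
})

test_that("adding the exposure term never lowers the log-likelihood", {
  ex <- simulate_exposure(500, seed = 91)
  cnt <- simulate_counts(ex, health_sim_config(400, alpha = log(20),
                                               beta1 = 0, seed = 92))
  t_num <- seq_len(nrow(cnt))
  B <- natural_spline_basis(t_num, 7)$design
  colnames(B) <- paste0("ns", 1:7)
  D <- dow_design(cnt$date)
  oz <- ex$value[match(cnt$date, ex$date)]
  base <- fit_poisson_loglinear(cnt$count, cbind(B, D))
  full <- fit_poisson_loglinear(cnt$count, cbind(ozone = oz, B, D))
  expect_gte(full$loglik, base$loglik - 1e-8)
})

test_that("lag fits guard against degenerate inputs", {
  ex <- simulate_exposure(120, seed = 101)
  cnt <- simulate_counts(ex, health_sim_config(100, alpha = log(10),
                                               beta1 = 0, seed = 102))
  expect_error(fit_single_lag(cnt, ex, lag = 0, df = 7), "insufficient")
  ex2 <- simulate_exposure(400, seed = 104)
  flat <- daily_series(ex2$date, rep(70, 400))
  cnt2 <- simulate_counts(flat, health_sim_config(390, alpha = log(10),
                                                  beta1 = 0, seed = 103))
  expect_error(fit_cumulative_lag(cnt2, flat, max_lag = 5, df = 7),
               "constant")
})

test_that("descriptive Pearson correlation behaves as the plain estimator", {
  expect_equal(pearson_descriptive(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_descriptive(c(1, 2, 3), c(-2, -4, -6)), -1)
  expect_equal(pearson_descriptive(c(1, 2, 3), c(2, 4, 7)), 0.99340,
               tolerance = 1e-5)
  expect_error(pearson_descriptive(c(1, 1, 1), c(2, 4, 7)), "variance")
  expect_error(pearson_descriptive(1:2, 2:3), "3 overlapping")
})

test_that("the reporting table formats every stratum across lags", {
  ex <- simulate_exposure(430, seed = 111)
  cnt <- simulate_counts(ex, health_sim_config(400, alpha = log(30),
                                               beta1 = 0.001, seed = 112))
  tab <- lag_effect_table(list(total = cnt), ex, max_lag = 2, df = 7)
  expect_equal(tab$wide$LAG, c("Lag0", "Lag1", "Lag2", "Lag02"))
  expect_match(tab$wide$total[1], "^\\d\\.\\d{3}\\(\\d\\.\\d{3},\\d\\.\\d{3}\\)$")
  expect_equal(nrow(tab$long), 4)
  expect_equal(tab$long$rr10, exp(10 * tab$long$beta))
})
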