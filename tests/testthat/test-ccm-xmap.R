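test_that("cross-mapping a series onto itself is near-perfect", {
  s <- simulate_coupled_maps(coupled_map_config(n = 700, burn_in = 200,
                                                seed = 3))
  emb <- delay_embed(s$x, E = 2, tau = 1)
  res <- cross_map(emb, s$x)
  expect_gt(res$rho, 0.99)
  expect_lt(res$p, 1e-10)
  expect_equal(res$n_pred, length(res$t_pred) - sum(is.na(res$estimates)))
})

test_that("cross-map skill between independent noise series is negligible", {
  set.seed(30)
  x <- rnorm(600)
  y <- rnorm(600)
  res <- cross_map(delay_embed(x, 2, 1), y)
  expect_lt(abs(res$rho), 0.15)
})

test_that("cross_map guards its inputs", {
  s <- rnorm(50)
  emb <- delay_embed(s, 2, 1)
  expect_error(cross_map(emb, rep(1, 50)), "zero variance")
  expect_error(cross_map(emb, s, lib = 1:3), "E \\+ 2")
})

test_that("skill significance matches the t reference and is odd in rho", {
  sig <- skill_significance(0.6, 102)
  expect_equal(sig$t_stat, 7.5)
  expect_equal(sig$p, 2 * pt(-7.5, df = 100))
  neg <- skill_significance(-0.6, 102)
  expect_equal(neg$t_stat, -7.5)
  expect_equal(neg$p, sig$p)
  expect_message(perfect <- skill_significance(1, 50), "rho")
  expect_equal(perfect$p, 0)
  expect_error(skill_significance(1.2, 50))
})

test_that("cross-map skill is invariant to affine maps of the target", {
  s <- simulate_coupled_maps(coupled_map_config(
    beta_xy = 0.32, n = 600, burn_in = 200, seed = 5))
  emb <- delay_embed(s$x, E = 2, tau = 1)
  r1 <- cross_map(emb, s$y)$rho
  r2 <- cross_map(emb, 10 + 3 * s$y)$rho
  expect_equal(r1, r2)
  # and to positive rescaling of the manifold series (distances scale)
  emb2 <- delay_embed(2 * s$x, E = 2, tau = 1)
  expect_equal(cross_map(emb2, s$y)$rho, r1)
})

test_that("the batched scan kernel reproduces the direct cross map bitwise", {
  s <- simulate_coupled_maps(coupled_map_config(
    beta_xy = 0.32, n = 500, burn_in = 200, seed = 8))
  nvec <- length(s$x) - 1  # E = 2, tau = 1
  cv <- convergence_scan(s$x, s$y, E = 2, tau = 1, L_grid = c(20, 50, nvec),
                         n_reps = 1, seed = 1)
  direct <- cross_map(delay_embed(s$x, 2, 1), s$y)
  expect_identical(cv$rho_reps[1, 3], direct$rho)
})

test_that("convergence scan is seed-deterministic with contract shapes", {
  s <- simulate_coupled_maps(coupled_map_config(
    beta_xy = 0.32, n = 500, burn_in = 200, seed = 12))
  cv <- convergence_scan(s$x, s$y, E = 2, tau = 2, L_grid = c(30, 80, 150),
                         n_reps = 10, seed = 7)
  cv2 <- convergence_scan(s$x, s$y, E = 2, tau = 2, L_grid = c(30, 80, 150),
                          n_reps = 10, seed = 7)
  expect_identical(cv$rho_reps, cv2$rho_reps)
  expect_equal(dim(cv$rho_reps), c(10, 3))
  expect_equal(cv$rho_mean, colMeans(cv$rho_reps))
  expect_error(convergence_scan(s$x, s$y, L_grid = c(80, 30)), "increasing")
  expect_error(convergence_scan(s$x, s$y, L_grid = c(30, 1e5)), "exceeds")
})

test_that("skill converges with library length only under coupling", {
  s <- simulate_coupled_maps(coupled_map_config(
    beta_xy = 0.32, n = 700, burn_in = 200, seed = 13))
  cv <- convergence_scan(s$x, s$y, E = 2, tau = 1,
                         L_grid = c(50, 120, 250, 400), n_reps = 40, seed = 1)
  gain <- cv$rho_mean[4] - cv$rho_mean[1]
  expect_gt(gain, 0.1)
  expect_gt(cv$rho_mean[4], 0.7)
  # uncoupled: flat, negligible skill throughout
  u <- simulate_coupled_maps(coupled_map_config(n = 700, burn_in = 200,
                                                seed = 13))
  cu <- convergence_scan(u$x, u$y, E = 2, tau = 1,
                         L_grid = c(50, 120, 250, 400), n_reps = 40, seed = 1)
  expect_lt(max(abs(cu$rho_mean)), 0.15)
})

test_that("detect_causality recovers one-way coupling direction", {
  s <- one_way_system(seed = 17)
  v <- detect_causality(s$x, s$y, E = 2, tau = 1, n_reps = 30, seed = 17)
  # y drives x (beta_xy couples y into x's map), so Mx encodes y
  expect_true(v$y_causes_x$causal)
  expect_false(v$x_causes_y$causal)
  expect_gt(v$y_causes_x$rho_at_max_L, v$x_causes_y$rho_at_max_L)
  expect_true(v$y_causes_x$convergence_pass)
  expect_true(v$y_causes_x$significance_pass)
})

test_that("detect_causality on uncoupled maps declares neither direction", {
  u <- simulate_coupled_maps(coupled_map_config(n = 900, burn_in = 200,
                                                seed = 19))
  v <- detect_causality(u$x, u$y, E = 2, tau = 1, n_reps = 30, seed = 19)
  expect_false(v$y_causes_x$causal)
  expect_false(v$x_causes_y$causal)
  expect_error(detect_causality(rep(1, 100), rnorm(100)), "constant")
})

test_that("identical series cross map symmetrically and perfectly", {
  s <- simulate_coupled_maps(coupled_map_config(n = 600, burn_in = 200,
                                                seed = 23))
  v <- detect_causality(s$x, s$x, E = 2, tau = 1, n_reps = 20, seed = 23)
  expect_gt(v$y_causes_x$rho_at_max_L, 0.99)
  expect_gt(v$x_causes_y$rho_at_max_L, 0.99)
})

test_that("curve export is tidy and loss-free", {
  s <- one_way_system(seed = 29, n = 500)
  cv <- convergence_scan(s$x, s$y, E = 2, tau = 1, L_grid = c(30, 100, 200),
                         n_reps = 5, seed = 2)
  long <- curve_to_long(cv, "y|Mx")
  expect_equal(nrow(long), 15)
  expect_equal(long$rho[long$L == 100], cv$rho_reps[, 2])
  expect_true(all(long$direction == "y|Mx"))
})
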