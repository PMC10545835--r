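test_that("fit configuration validates bounds and defaults to printed ranges", {
  cfg <- fit_config()
  expect_equal(cfg$mu_s_bounds, c(0.1, 10))
  expect_equal(cfg$mu_a_bounds, c(1e-4, 0.1))
  expect_equal(cfg$init_mu_s, 1.0)
  expect_equal(cfg$init_mu_a, 0.01)
  expect_error(fit_config(mu_s_bounds = c(-1, 2)), "0 < low < high")
  expect_error(fit_config(init_mu_s = 20), "outside")
})

test_that("residuals vanish at the generating parameters", {
  grid <- quick_grid()
  irf <- make_gaussian_irf(grid)
  geom <- quick_geom(51)
  y <- quick_synthetic_trp(mu_a = 0.010, mu_s = 0.60, s = 51,
                           grid = grid, irf = irf)
  amp <- max(y$counts) / max(convolve_with_irf(
    transmittance_curve(grid_times(grid), optical_properties(0.01, 0.6), geom),
    irf, grid))
  r <- residual_vector(c(mu_a = 0.010, mu_s_prime = 0.60, amplitude = amp),
                       y, irf, geom)
  expect_lt(max(abs(r)) / max(y$counts), 1e-9)

  # truth beats 20% scattering perturbations on noiseless input
  rss <- function(mu_s) sum(residual_vector(
    c(mu_a = 0.010, mu_s_prime = mu_s, amplitude = amp), y, irf, geom)^2)
  expect_lt(rss(0.60), rss(0.48))
  expect_lt(rss(0.60), rss(0.72))

  # doubling amplitude doubles the model side exactly
  pred1 <- y$counts - residual_vector(
    c(mu_a = 0.01, mu_s_prime = 0.6, amplitude = amp), y, irf, geom)
  pred2 <- y$counts - residual_vector(
    c(mu_a = 0.01, mu_s_prime = 0.6, amplitude = 2 * amp), y, irf, geom)
  expect_equal(pred2, 2 * pred1)
})

test_that("noiseless fits recover the generating optical properties", {
  grid <- quick_grid()
  irf <- make_gaussian_irf(grid)
  for (mu_s in c(0.3, 1.0)) for (mu_a in c(0.005, 0.02)) for (s in c(45, 55)) {
    y <- quick_synthetic_trp(mu_a = mu_a, mu_s = mu_s, s = s,
                             grid = grid, irf = irf)
    f <- fit_optical_properties(y, irf, quick_geom(s))
    expect_true(f$converged)
    expect_lt(abs(f$props$mu_s_prime - mu_s) / mu_s, 0.005)
    expect_lt(abs(f$props$mu_a - mu_a) / mu_a, 0.02)
  }
})

test_that("count scaling moves the amplitude only", {
  grid <- quick_grid()
  irf <- make_gaussian_irf(grid)
  geom <- quick_geom(51)
  y <- quick_synthetic_trp(grid = grid, irf = irf)
  f1 <- fit_optical_properties(y, irf, geom)
  y2 <- trp(grid, 3.7 * y$counts, y$meta)
  f2 <- fit_optical_properties(y2, irf, geom)
  expect_equal(f2$amplitude / f1$amplitude, 3.7, tolerance = 1e-6)
  expect_equal(f2$props$mu_s_prime, f1$props$mu_s_prime, tolerance = 1e-6)
  expect_equal(f2$props$mu_a, f1$props$mu_a, tolerance = 1e-6)
})

test_that("starved photon counts yield usable quality diagnostics", {
  grid <- quick_grid()
  irf <- make_gaussian_irf(grid)
  geom <- quick_geom(51)
  model <- convolve_with_irf(
    transmittance_curve(grid_times(grid), optical_properties(0.01, 0.6), geom),
    irf, grid)
  y <- trp(grid, simulate_counts(model, 500, 4))
  f <- fit_optical_properties(y, irf, geom)
  expect_type(f$converged, "logical")
  expect_type(f$at_bound, "character")
  expect_gte(f$residual_norm, 0)
  expect_error(fit_optical_properties(trp(grid, rep(0, grid$n_bins)),
                                      irf, geom), "no counts")
})

test_that("poisson-weighted loss is available and sane", {
  grid <- quick_grid()
  irf <- make_gaussian_irf(grid)
  geom <- quick_geom(51)
  model <- convolve_with_irf(
    transmittance_curve(grid_times(grid), optical_properties(0.01, 0.6), geom),
    irf, grid)
  y <- trp(grid, simulate_counts(model, 1e6, 9))
  f <- fit_optical_properties(y, irf, geom,
                              fit_config(poisson_weights = TRUE))
  expect_true(f$converged)
  expect_lt(abs(f$props$mu_s_prime - 0.6) / 0.6, 0.05)
})
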