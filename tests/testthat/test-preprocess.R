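test_that("savitzky-golay interior weights solve the local quadratic fit", {
  # brute-force oracle: project onto polynomials on the centered window
  brute_sg_center <- function(p, n) {
    half <- (n - 1) / 2
    X <- outer(-half:half, 0:p, "^")
    H <- X %*% solve(crossprod(X)) %*% t(X)
    H[half + 1, ]
  }
  expect_equal(sg_coefficients(2, 5), brute_sg_center(2, 5), tolerance = 1e-12)
  expect_equal(sg_coefficients(2, 5), c(-3, 12, 17, 12, -3) / 35,
               tolerance = 1e-12)
  expect_equal(sg_coefficients(3, 9), brute_sg_center(3, 9), tolerance = 1e-12)
})

test_that("smoothing reproduces constants and lines and keeps the grid", {
  grid <- quick_grid(64L)
  const <- trp(grid, rep(7, 64), list(sample_id = "c"))
  expect_equal(savitzky_golay_smooth(const)$counts, rep(7, 64))
  ramp <- trp(grid, seq(0, 63) * 2, list(sample_id = "r"))
  expect_equal(savitzky_golay_smooth(ramp)$counts, seq(0, 63) * 2)
  expect_identical(savitzky_golay_smooth(ramp)$meta$sample_id, "r")
  short <- trp(time_grid(0, 10.3, 8L), rep(1, 8))
  expect_error(savitzky_golay_smooth(short, frame_length = 9), "shorter|exceed")
})

test_that("smoothing approximately preserves mass of a noisy plateau", {
  grid <- quick_grid(200L)
  set.seed(3)
  y <- 1000 + rnorm(200, 0, 10)
  sm <- savitzky_golay_smooth(trp(grid, y))
  expect_lt(abs(sum(sm$counts) - sum(y)) / sum(y), 1e-3)
})

test_that("background subtraction recovers a constant-offset profile", {
  grid <- quick_grid(128L)
  base <- quick_synthetic_trp(grid = grid, amplitude = 1e3,
                              irf = make_gaussian_irf(grid, center = 200))
  shifted <- trp(grid, base$counts + 12.5, base$meta)
  rec <- subtract_background(shifted, 1:10)
  expect_equal(rec$counts, pmax(base$counts, 0), tolerance = 1e-10)
  # clamping never leaves negatives
  expect_true(all(subtract_background(shifted, 1:10)$counts >= 0))
  zero_bg <- subtract_background(base, 1:3)
  expect_equal(zero_bg$counts, base$counts)
  flat <- trp(grid, rep(5, 128))
  expect_warning(subtract_background(flat, 1:10), "50%")
})

test_that("difference profiles subtract day 0 and keep day-d metadata", {
  grid <- quick_grid(128L)
  irf <- make_gaussian_irf(grid, center = 200)
  p0 <- quick_synthetic_trp(mu_s = 0.8, grid = grid, irf = irf,
                            meta = list(sample_id = "s1", day = 0, condition = "shelf"))
  pd <- quick_synthetic_trp(mu_s = 0.5, grid = grid, irf = irf,
                            meta = list(sample_id = "s1", day = 9, condition = "shelf"))
  d <- difference_profile(pd, p0)
  expect_s3_class(d, "difference_profile")
  expect_equal(d$delta_counts, pd$counts - p0$counts)
  expect_identical(d$meta$day, 9)

  # self-difference is identically zero; antisymmetry
  expect_true(all(difference_profile(p0, p0)$delta_counts == 0))
  expect_equal(difference_profile(p0, pd)$delta_counts, -d$delta_counts)

  other <- quick_synthetic_trp(grid = grid, irf = irf,
                               meta = list(sample_id = "s2", day = 0))
  expect_error(difference_profile(pd, other), "sample ids")
})

test_that("softening raises peak-region intensity in difference spectra", {
  # lower mu_s' (softer fruit) transmits more light at fixed illumination
  grid <- quick_grid()
  irf <- make_gaussian_irf(grid)
  tt <- grid_times(grid)
  geom <- quick_geom(51)
  f0 <- convolve_with_irf(transmittance_curve(tt, optical_properties(0.01, 0.8), geom), irf, grid)
  fd <- convolve_with_irf(transmittance_curve(tt, optical_properties(0.01, 0.45), geom), irf, grid)
  scale <- 1e6 / sum(f0)  # fixed source strength calibrated on day 0
  d <- scale * (fd - f0)
  peak_region <- which(f0 > 0.5 * max(f0))
  expect_true(all(d[peak_region] > 0))
})
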