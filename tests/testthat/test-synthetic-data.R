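test_that("scattering trajectories decay from mu_s0 toward the floor", {
  expect_equal(mu_s_trajectory(0, 0.75, 0.35, 6), 0.75)
  expect_equal(mu_s_trajectory(1e6, 0.75, 0.35, 6), 0.35)
  d <- c(0, 3, 6, 12)
  expect_true(all(diff(mu_s_trajectory(d, 0.9, 0.35, 6)) < 0))
  expect_error(mu_s_trajectory(1, 0.75, 0.35, -2), "tau")
  expect_error(mu_s_trajectory(1, 0.3, 0.35, 6), "floor")
  # jitter is seeded and has roughly the requested CV
  set.seed(1)
  j <- mu_s_trajectory(rep(5, 2000), 0.75, 0.35, 6, jitter_cv = 0.10)
  expect_equal(sd(j) / mean(j), 0.10, tolerance = 0.06)
  expect_identical(mu_s_trajectory(1:4, 0.75, 0.35, 6, 0.1, rng_seed = 9),
                   mu_s_trajectory(1:4, 0.75, 0.35, 6, 0.1, rng_seed = 9))
})

test_that("generated studies are deterministic and structurally complete", {
  cfg <- quick_study_config(seed = 11L)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$trps[[1]]$counts, s2$trps[[1]]$counts)

  # every record has a TRP; truth aligned with records
  expect_equal(nrow(s1$records), 3L * 4L * 2L)
  expect_equal(length(s1$trps), nrow(s1$records))
  expect_identical(s1$truth$sample_id, s1$records$sample_id)

  # latent scattering within the physical range the config implies
  expect_true(all(s1$truth$mu_s_prime <= cfg$mu_s0_clip[2]))
  expect_true(all(s1$truth$mu_s_prime >= cfg$mu_s_floor / 2))
  day0 <- s1$truth$day == 0
  expect_true(all(s1$truth$mu_s_prime[day0] >= cfg$mu_s0_clip[1] * (1 - 3 * cfg$jitter_cv)))

  expect_error(study_config(mu_a_mean = -1), "mu_a_mean")
})

test_that("firmness tracks the latent scattering and color trends are weak", {
  study <- generate_study(study_config(n_samples = 10L, seed = 3L))
  m <- merge(study$records, study$truth,
             by = c("sample_id", "condition", "day"))
  expect_gt(cor(m$firmness_N_cm2, m$mu_s_prime), 0.8)
  # per-sample color-vs-day correlations fluctuate around small values
  shelf <- study$records[study$records$condition == "shelf", ]
  r_L <- vapply(split(shelf, shelf$sample_id),
                function(d) cor(d$day, d$L_star), numeric(1))
  expect_lt(abs(median(r_L)), 0.6)
})

test_that("softening is faster under shelf life than cold storage", {
  r_means <- sapply(1:6, function(s) {
    study <- generate_study(study_config(n_samples = 6L, seed = 100L + s))
    tr <- study$truth
    by_cond <- sapply(c("shelf", "cold"), function(cc) {
      d <- tr[tr$condition == cc, ]
      mean(vapply(split(d, d$sample_id),
                  function(x) cor(x$day, x$mu_s_prime), numeric(1)))
    })
    by_cond
  })
  # averaged over studies, shelf-life decay correlations are more negative
  expect_lt(mean(r_means["shelf", ]), mean(r_means["cold", ]))
})

test_that("fixtures round-trip losslessly through the readers", {
  study <- generate_study(quick_study_config(seed = 5L))
  dir <- tempfile("fixture_")
  write_fixture(study, dir)
  expect_error(write_fixture(study, dir), "overwrite")
  back <- read_study_fixture(dir)
  expect_equal(back$records$firmness_N_cm2, study$records$firmness_N_cm2,
               tolerance = 1e-6)
  key <- names(study$trps)[7]
  expect_equal(back$trps[[key]]$counts, study$trps[[key]]$counts)
  expect_equal(back$truth$mu_s_prime, study$truth$mu_s_prime, tolerance = 1e-6)
  expect_equal(sum(back$irf$weights), 1)

  # truth withheld on request
  dir2 <- tempfile("fixture_")
  write_fixture(study, dir2, export_truth = FALSE)
  expect_null(read_study_fixture(dir2)$truth)
  # expected file count: one TRP per (sample, day) pair
  expect_equal(length(dir(file.path(dir2, "trp"))), nrow(study$records))
})
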