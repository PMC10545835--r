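# Synthetic storage studies: latent optical-property trajectories, rendered
# TRPs with Poisson counting noise, and linked destructive/color phenotypes.
# The generator gives every pipeline stage a complete, statistically
# realistic input without any instrument data.

#' Synthetic-study configuration
#'
#' Defaults emulate a two-condition kiwifruit storage trial: ten fruit per
#' condition, shelf-life measurements on days 0, 1, 3, ..., 13 and cold
#' storage on days 0, 7, ..., 49. Each fruit's reduced scattering coefficient
#' starts from a fruit-specific day-0 value (clipped normal around
#' 0.75 mm^-1, spanning roughly 0.45-1.15 mm^-1) and relaxes exponentially
#' toward a floor of 0.35 mm^-1 with a condition-specific time constant
#' (6 d shelf, 30 d cold: softening is faster at room temperature), times
#' lognormal measurement jitter. Absorption is weak and day-independent
#' (clipped normal around 0.010 mm^-1). Firmness is an affine decreasing
#' function of the latent mu_s' plus noise; skin color carries only weak day
#' trends with large fluctuation, mimicking how little kiwifruit skin color
#' changes during ripening.
#'
#' @param n_samples fruit per condition.
#' @param shelf_days,cold_days measurement day grids.
#' @param mu_s0_mean,mu_s0_sd,mu_s0_clip day-0 mu_s' distribution, mm^-1.
#' @param mu_s_floor asymptotic mu_s', mm^-1.
#' @param tau_shelf,tau_cold softening time constants, days.
#' @param jitter_cv lognormal measurement jitter CV on mu_s'.
#' @param mu_a_mean,mu_a_sd,mu_a_clip absorption distribution, mm^-1.
#' @param diameter_mean,diameter_sd,diameter_clip fruit diameter, mm.
#' @param firmness_intercept,firmness_slope,firmness_sd firmness link:
#'   `firmness = intercept + slope * (mu_s' - 0.2) + N(0, sd)`, N/cm^2.
#' @param total_counts expected photons per acquisition for a reference fruit
#'   (mean day-0 optics, mean diameter); the source strength is calibrated
#'   once from this value, so actual per-TRP totals rise as the fruit softens
#'   and scattering falls, as they do at fixed illumination and counting time.
#' @param irf_fwhm,irf_center Gaussian IRF shape, ps.
#' @param grid the acquisition [time_grid].
#' @param seed integer seed fixing the whole study.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_samples = 10L,
                         shelf_days = c(0, 1, 3, 5, 7, 9, 11, 13),
                         cold_days = seq(0, 49, by = 7),
                         mu_s0_mean = 0.75, mu_s0_sd = 0.15,
                         mu_s0_clip = c(0.45, 1.15),
                         mu_s_floor = 0.35,
                         tau_shelf = 6, tau_cold = 30,
                         jitter_cv = 0.10,
                         mu_a_mean = 0.010, mu_a_sd = 0.003,
                         mu_a_clip = c(0.003, 0.023),
                         diameter_mean = 51, diameter_sd = 0.7,
                         diameter_clip = c(49, 53),
                         firmness_intercept = 2, firmness_slope = 35,
                         firmness_sd = 2,
                         total_counts = 1e6,
                         irf_fwhm = 159.83, irf_center = 500,
                         grid = default_time_grid(),
                         seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              shelf_days = sort(shelf_days), cold_days = sort(cold_days),
              mu_s0_mean = mu_s0_mean, mu_s0_sd = mu_s0_sd,
              mu_s0_clip = mu_s0_clip, mu_s_floor = mu_s_floor,
              tau_shelf = tau_shelf, tau_cold = tau_cold,
              jitter_cv = jitter_cv,
              mu_a_mean = mu_a_mean, mu_a_sd = mu_a_sd, mu_a_clip = mu_a_clip,
              diameter_mean = diameter_mean, diameter_sd = diameter_sd,
              diameter_clip = diameter_clip,
              firmness_intercept = firmness_intercept,
              firmness_slope = firmness_slope, firmness_sd = firmness_sd,
              total_counts = total_counts,
              irf_fwhm = irf_fwhm, irf_center = irf_center,
              grid = grid, seed = as.integer(seed))
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  pos <- c("mu_s0_mean", "mu_s0_sd", "mu_s_floor", "tau_shelf", "tau_cold",
           "mu_a_mean", "mu_a_sd", "diameter_mean", "diameter_sd",
           "firmness_sd", "total_counts", "irf_fwhm")
  for (nm in pos) if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
    stop("study_config field '", nm, "' must be a positive number")
  if (cfg$n_samples < 1L) stop("study_config field 'n_samples' must be >= 1")
  if (cfg$jitter_cv < 0) stop("study_config field 'jitter_cv' must be >= 0")
  if (cfg$mu_s_floor >= cfg$mu_s0_clip[1L])
    stop("study_config: mu_s_floor must lie below the mu_s0 clip range")
  if (is.unsorted(cfg$shelf_days) || is.unsorted(cfg$cold_days))
    stop("study_config: day grids must be sorted")
  invisible(cfg)
}

#' Latent reduced-scattering trajectory
#'
#' `floor + (mu_s0 - floor) * exp(-day / tau)`, multiplied by lognormal
#' jitter with the given coefficient of variation: monotone exponential
#' softening of the scattering coefficient with fruit-specific start and
#' condition-specific rate.
#'
#' @param day storage day(s).
#' @param mu_s0 day-0 value, mm^-1.
#' @param floor asymptote, mm^-1 (0 < floor < mu_s0).
#' @param tau time constant, days (> 0).
#' @param jitter_cv lognormal jitter CV (0 disables jitter).
#' @param rng_seed integer seed used when jitter is drawn.
#' @return mu_s' value(s), mm^-1.
#' @export
mu_s_trajectory <- function(day, mu_s0, floor, tau, jitter_cv = 0,
                            rng_seed = NULL) {
  if (tau <= 0) stop("tau must be positive")
  if (floor <= 0 || floor >= mu_s0) stop("need 0 < floor < mu_s0")
  base <- floor + (mu_s0 - floor) * exp(-day / tau)
  if (jitter_cv > 0) {
    if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
    sdlog <- sqrt(log(1 + jitter_cv^2))
    base <- base * stats::rlnorm(length(base), meanlog = -sdlog^2 / 2,
                                 sdlog = sdlog)
  }
  base
}

rnorm_clipped <- function(n, mean, sd, clip) {
  pmin(pmax(stats::rnorm(n, mean, sd), clip[1L]), clip[2L])
}

trp_key <- function(sample_id, day) paste0(sample_id, "_d", day)

#' Generate a complete synthetic storage study
#'
#' Draws per-fruit day-0 scattering values and diameters, evolves the latent
#' (mu_a, mu_s') over each condition's day grid, renders every TRP as the
#' slab transmittance (thickness = that fruit's diameter) convolved with a
#' shared Gaussian IRF, scaled by a fixed per-study source strength and
#' Poisson-sampled, and attaches linked phenotypes (firmness tied to latent
#' mu_s'; SSC, pH and skin color with weak day trends and sizable noise).
#' Fully deterministic for a given config seed.
#'
#' @param config a [study_config].
#' @return An object of class `study_dataset`: `records` (data.frame of
#'   sample metadata and phenotypes), `trps` (named list of [trp]s keyed
#'   `<sample>_d<day>`), `irf`, `truth` (data.frame of latent optical
#'   properties; synthetic data only), `config`.
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  validate_study_config(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  irf <- make_gaussian_irf(config$grid, config$irf_fwhm, config$irf_center)
  times <- grid_times(config$grid)
  conv_mat <- irf_convolution_matrix(irf, config$grid$n_bins)

  # fixed-illumination calibration: the source strength is set once so that a
  # reference fruit (mean day-0 optics, mean diameter) yields `total_counts`
  # expected photons in one acquisition. Softer fruit (lower mu_s') then
  # transmit more photons, reproducing the intensity up-shift with storage
  # that the difference-spectra analysis relies on.
  ref_curve <- transmittance_curve(
    times, optical_properties(config$mu_a_mean, config$mu_s0_mean),
    slab_geometry(config$diameter_mean))
  source_strength <- config$total_counts / sum(as.vector(conv_mat %*% ref_curve))

  conditions <- list(shelf = list(days = config$shelf_days, tau = config$tau_shelf),
                     cold = list(days = config$cold_days, tau = config$tau_cold))
  records <- list(); truth <- list(); trps <- list()

  for (cond in names(conditions)) {
    days <- conditions[[cond]]$days
    tau <- conditions[[cond]]$tau
    for (i in seq_len(config$n_samples)) {
      sid <- sprintf("%s_%02d", cond, i)
      mu_s0 <- rnorm_clipped(1L, config$mu_s0_mean, config$mu_s0_sd,
                             config$mu_s0_clip)
      diam <- rnorm_clipped(1L, config$diameter_mean, config$diameter_sd,
                            config$diameter_clip)
      geom <- slab_geometry(thickness_s = diam)
      ssc0 <- stats::rnorm(1L, 13, 1.2)
      for (d in days) {
        mu_s <- mu_s_trajectory(d, mu_s0, config$mu_s_floor, tau,
                                config$jitter_cv)
        # measurement jitter can overshoot the physical range; clamp the
        # latent value to [floor/2, clip high]
        mu_s <- min(max(mu_s, config$mu_s_floor / 2), config$mu_s0_clip[2L])
        mu_a <- rnorm_clipped(1L, config$mu_a_mean, config$mu_a_sd,
                              config$mu_a_clip)
        props <- optical_properties(mu_a, mu_s)
        expected <- as.vector(conv_mat %*% transmittance_curve(times, props, geom))
        seed_trp <- (as.numeric(config$seed) * 1009 +
                       length(trps) * 7919) %% 2147483647
        counts <- simulate_counts(expected, source_strength * sum(expected),
                                  seed_trp)
        key <- trp_key(sid, d)
        trps[[key]] <- trp(config$grid, counts,
                           list(sample_id = sid, day = d, condition = cond))
        firmness <- max(config$firmness_intercept +
                          config$firmness_slope * (mu_s - 0.2) +
                          stats::rnorm(1L, 0, config$firmness_sd), 0.5)
        records[[length(records) + 1L]] <- data.frame(
          sample_id = sid, condition = cond, day = d, diameter_mm = diam,
          firmness_N_cm2 = firmness,
          ssc_brix = ssc0 + stats::rnorm(1L, 0, 0.4),
          ph = 3.2 + 0.012 * d + stats::rnorm(1L, 0, 0.12),
          L_star = 58 - 0.05 * d + stats::rnorm(1L, 0, 1.8),
          a_star = 5.5 + 0.02 * d + stats::rnorm(1L, 0, 1.1),
          b_star = 21 + 0.03 * d + stats::rnorm(1L, 0, 1.6))
        truth[[length(truth) + 1L]] <- data.frame(
          sample_id = sid, condition = cond, day = d,
          mu_a = mu_a, mu_s_prime = mu_s)
      }
    }
  }
  structure(list(records = do.call(rbind, records),
                 trps = trps, irf = irf,
                 truth = do.call(rbind, truth),
                 config = config),
            class = "study_dataset")
}

#' Write a study to a plain-text fixture directory
#'
#' Emits `manifest.csv`, `irf.csv`, optionally `truth.csv`, and one
#' `trp/<sample>_d<day>.csv` per profile, all in the shared two-column CSV
#' dialect; the layout round-trips losslessly through
#' [read_study_fixture()].
#'
#' @param study a `study_dataset`.
#' @param directory target directory.
#' @param export_truth include the latent-truth table (default TRUE).
#' @param overwrite allow writing into an existing non-empty directory.
#' @return The manifest path, invisibly.
#' @export
write_fixture <- function(study, directory, export_truth = TRUE,
                          overwrite = FALSE) {
  stopifnot(inherits(study, "study_dataset"))
  if (dir.exists(directory) && length(dir(directory)) > 0L && !overwrite)
    stop("directory exists and is not empty; set overwrite = TRUE")
  dir.create(file.path(directory, "trp"), recursive = TRUE, showWarnings = FALSE)
  manifest <- study$records
  manifest$trp_path <- file.path("trp", paste0(
    trp_key(manifest$sample_id, manifest$day), ".csv"))
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  write_trp_csv(grid_times(study$irf$grid), study$irf$weights,
                file.path(directory, "irf.csv"))
  if (export_truth)
    utils::write.csv(study$truth, file.path(directory, "truth.csv"),
                     row.names = FALSE, quote = FALSE)
  for (key in names(study$trps)) {
    p <- study$trps[[key]]
    write_trp_csv(grid_times(p$grid), p$counts,
                  file.path(directory, "trp", paste0(key, ".csv")))
  }
  invisible(file.path(directory, "manifest.csv"))
}
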