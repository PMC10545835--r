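# Per-TRP estimation of (mu_a, mu_s') by bounded nonlinear least squares on
# the IRF-convolved slab transmittance.

#' Inverse-fit configuration
#'
#' Box bounds, starting values and convergence settings for the optical
#' property fit. The default bounds are the standard search ranges for fruit
#' tissue at NIR wavelengths where scattering dominates absorption:
#' mu_s' in [0.1, 10] mm^-1 and mu_a in [0.0001, 0.1] mm^-1. Starting values
#' default to the geometric midpoints of those ranges (1.0 and 0.01 mm^-1).
#'
#' @param mu_s_bounds length-2 numeric, (low, high) for mu_s', mm^-1.
#' @param mu_a_bounds length-2 numeric, (low, high) for mu_a, mm^-1.
#' @param init_mu_s,init_mu_a starting values, inside the bounds.
#' @param fit_amplitude fit a free multiplicative amplitude (default TRUE);
#'   absolute recorded counts depend on source power and acquisition time, so
#'   the model scale is not known a priori.
#' @param fit_time_shift fit a trigger-misalignment time shift, ps
#'   (default FALSE).
#' @param poisson_weights use 1/sqrt(counts) residual weighting instead of
#'   unweighted least squares (default FALSE).
#' @param max_iterations iteration cap (default 1000).
#' @param tolerance relative convergence threshold on parameters and cost
#'   (default 1e-8).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(mu_s_bounds = c(0.1, 10), mu_a_bounds = c(1e-4, 0.1),
                       init_mu_s = 1.0, init_mu_a = 0.01,
                       fit_amplitude = TRUE, fit_time_shift = FALSE,
                       poisson_weights = FALSE,
                       max_iterations = 1000L, tolerance = 1e-8) {
  chk <- function(b, nm) {
    if (length(b) != 2L || !(0 < b[1L] && b[1L] < b[2L]))
      stop(sprintf("%s must satisfy 0 < low < high", nm))
  }
  chk(mu_s_bounds, "mu_s_bounds"); chk(mu_a_bounds, "mu_a_bounds")
  if (init_mu_s < mu_s_bounds[1L] || init_mu_s > mu_s_bounds[2L])
    stop("init_mu_s outside mu_s_bounds")
  if (init_mu_a < mu_a_bounds[1L] || init_mu_a > mu_a_bounds[2L])
    stop("init_mu_a outside mu_a_bounds")
  structure(list(mu_s_bounds = mu_s_bounds, mu_a_bounds = mu_a_bounds,
                 init_mu_s = init_mu_s, init_mu_a = init_mu_a,
                 fit_amplitude = isTRUE(fit_amplitude),
                 fit_time_shift = isTRUE(fit_time_shift),
                 poisson_weights = isTRUE(poisson_weights),
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance),
            class = "fit_config")
}

# model prediction on the TRP grid: amplitude * (slab model (x) IRF), with an
# optional time shift applied to the model before convolution
predict_convolved <- function(mu_a, mu_s, amplitude, time_shift,
                              times, conv_mat, geom) {
  props <- optical_properties(mu_a, mu_s)
  model <- transmittance_curve_shifted(times - time_shift, props, geom)
  amplitude * as.vector(conv_mat %*% model)
}

# transmittance on a possibly unsorted / shifted time vector
transmittance_curve_shifted <- function(t, props, geom) {
  ord <- order(t)
  out <- numeric(length(t))
  out[ord] <- transmittance_curve(t[ord], props, geom)
  out
}

#' Residual vector of the convolved-model fit
#'
#' `measured counts - amplitude * (model (x) IRF)` over the entire grid (the
#' whole TRP is used for fitting, not a windowed portion).
#'
#' @param params named numeric vector with `mu_a`, `mu_s_prime`, `amplitude`
#'   and optionally `time_shift` (ps).
#' @param trp a [trp].
#' @param irf an [instrument_response] on the same bin width.
#' @param geom a [slab_geometry]; `thickness_s` is the sample diameter.
#' @return Numeric residuals, one per bin.
#' @export
residual_vector <- function(params, trp, irf, geom) {
  stopifnot(inherits(trp, "trp"))
  times <- grid_times(trp$grid)
  conv_mat <- irf_convolution_matrix(irf, trp$grid$n_bins)
  shift <- if ("time_shift" %in% names(params)) params[["time_shift"]] else 0
  pred <- predict_convolved(params[["mu_a"]], params[["mu_s_prime"]],
                            params[["amplitude"]], shift,
                            times, conv_mat, geom)
  trp$counts - pred
}

#' Fit optical properties to a TRP
#'
#' Box-constrained least squares (Levenberg-Marquardt with bound projection)
#' of the IRF-convolved slab transmittance against a measured TRP. Free
#' parameters are mu_a, mu_s' and (by default) a multiplicative amplitude;
#' an optional time shift absorbs IRF/TRP trigger misalignment. Convergence
#' failure is reported through `converged = FALSE`, never silently; estimates
#' that stick to a box bound are named in `at_bound`.
#'
#' @param trp a [trp] with positive total counts.
#' @param irf an [instrument_response] sharing the TRP's bin width.
#' @param geom a [slab_geometry] whose `thickness_s` is the measured sample
#'   diameter (the optical path correction).
#' @param config a [fit_config].
#' @return An object of class `fit_result`: fields `props`
#'   ([optical_properties]), `amplitude`, `time_shift`, `residual_norm` (sum
#'   of squared residuals), `converged`, `n_iterations`, `at_bound`
#'   (character vector of bound-stuck parameter names).
#' @export
fit_optical_properties <- function(trp, irf, geom, config = fit_config()) {
  stopifnot(inherits(trp, "trp"), inherits(irf, "instrument_response"),
            inherits(geom, "slab_geometry"), inherits(config, "fit_config"))
  if (!same_spacing(trp$grid, irf$grid)) stop("TRP and IRF grid spacings differ")
  if (sum(trp$counts) <= 0) stop("TRP has no counts: nothing to fit")

  times <- grid_times(trp$grid)
  conv_mat <- irf_convolution_matrix(irf, trp$grid$n_bins)
  wts <- if (config$poisson_weights) 1 / sqrt(pmax(trp$counts, 1)) else NULL

  # amplitude start from total-count matching at the initial optical properties
  base <- predict_convolved(config$init_mu_a, config$init_mu_s, 1, 0,
                            times, conv_mat, geom)
  amp0 <- sum(trp$counts) / max(sum(base), .Machine$double.xmin)

  par0 <- c(mu_a = config$init_mu_a, mu_s_prime = config$init_mu_s,
            amplitude = amp0)
  lower <- c(config$mu_a_bounds[1L], config$mu_s_bounds[1L], 0)
  upper <- c(config$mu_a_bounds[2L], config$mu_s_bounds[2L], Inf)
  if (config$fit_time_shift) {
    par0 <- c(par0, time_shift = 0)
    span <- times[length(times)] - times[1L]
    lower <- c(lower, -span / 4); upper <- c(upper, span / 4)
  }
  if (!config$fit_amplitude) {
    lower[3L] <- amp0 * (1 - 1e-12); upper[3L] <- amp0 * (1 + 1e-12)
  }

  fn <- function(p) {
    shift <- if (config$fit_time_shift) p[[4L]] else 0
    r <- trp$counts - predict_convolved(p[[1L]], p[[2L]], p[[3L]], shift,
                                        times, conv_mat, geom)
    if (is.null(wts)) r else r * wts
  }

  out <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = fn,
    control = minpack.lm::nls.lm.control(
      maxiter = min(config$max_iterations, 1024L),
      ftol = config$tolerance, ptol = config$tolerance, maxfev = 100000L))

  est <- out$par
  converged <- out$info %in% c(1L, 2L, 3L, 4L)
  at_bound <- character(0)
  tol_b <- 1e-6
  if (est[["mu_a"]] <= lower[1L] * (1 + tol_b) ||
      est[["mu_a"]] >= upper[1L] * (1 - tol_b)) at_bound <- c(at_bound, "mu_a")
  if (est[["mu_s_prime"]] <= lower[2L] * (1 + tol_b) ||
      est[["mu_s_prime"]] >= upper[2L] * (1 - tol_b)) at_bound <- c(at_bound, "mu_s_prime")

  structure(list(
    props = optical_properties(est[["mu_a"]], est[["mu_s_prime"]]),
    amplitude = est[["amplitude"]],
    time_shift = if (config$fit_time_shift) est[["time_shift"]] else 0,
    residual_norm = out$deviance,
    converged = converged,
    n_iterations = out$niter,
    at_bound = at_bound,
    message = out$message),
    class = "fit_result")
}

#' Fit every TRP of a study
#'
#' Convenience loop over a study's (sample, day) TRPs; returns the
#' machine-readable analogue of a per-study optical-property table.
#'
#' @param study a `study_dataset` (see [generate_study()] or
#'   [read_study_fixture()]).
#' @param config a [fit_config].
#' @param geom_defaults a [slab_geometry] template; `thickness_s` is replaced
#'   per sample by the manifest diameter.
#' @return A data.frame with columns `sample_id`, `condition`, `day`,
#'   `diameter_mm`, `mu_a`, `mu_s_prime`, `amplitude`, `residual_norm`,
#'   `converged`.
#' @export
fit_study <- function(study, config = fit_config(),
                      geom_defaults = slab_geometry(50)) {
  stopifnot(inherits(study, "study_dataset"))
  recs <- study$records
  res <- vector("list", nrow(recs))
  for (i in seq_len(nrow(recs))) {
    key <- trp_key(recs$sample_id[i], recs$day[i])
    profile <- study$trps[[key]]
    if (is.null(profile)) stop("missing TRP for ", key)
    geom <- slab_geometry(thickness_s = recs$diameter_mm[i],
                          rho = geom_defaults$rho,
                          refractive_index_n = geom_defaults$refractive_index_n,
                          boundary_A = geom_defaults$boundary_A,
                          dipole_max_m = geom_defaults$dipole_max_m)
    fit <- fit_optical_properties(profile, study$irf, geom, config)
    res[[i]] <- data.frame(
      sample_id = recs$sample_id[i], condition = recs$condition[i],
      day = recs$day[i], diameter_mm = recs$diameter_mm[i],
      mu_a = fit$props$mu_a, mu_s_prime = fit$props$mu_s_prime,
      amplitude = fit$amplitude, residual_norm = fit$residual_norm,
      converged = fit$converged)
  }
  do.call(rbind, res)
}
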