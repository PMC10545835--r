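# Time grids, time-resolved profiles (TRPs), the instrument response function
# (IRF), model-IRF convolution and photon-counting noise.

#' Uniform time grid
#'
#' @param t0 time of the first bin, ps.
#' @param dt bin width, ps (> 0).
#' @param n_bins number of bins (>= 8).
#' @return An object of class `time_grid`.
#' @examples
#' default_time_grid()   # the streak-camera style 0-5 ns, 10.3 ps grid
#' @export
time_grid <- function(t0 = 0, dt = 10.3, n_bins = 486L) {
  stopifnot(is.numeric(t0), is.numeric(dt), length(dt) == 1L)
  if (dt <= 0) stop("dt must be positive")
  n_bins <- as.integer(n_bins)
  if (n_bins < 8L) stop("n_bins must be at least 8")
  structure(list(t0 = t0, dt = dt, n_bins = n_bins), class = "time_grid")
}

#' @rdname time_grid
#' @export
default_time_grid <- function() time_grid(0, 10.3, 486L)

#' Times of a grid's bins
#' @param grid a [time_grid].
#' @return Numeric vector `t0 + (0:(n_bins-1)) * dt`, ps.
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  grid$t0 + seq.int(0L, grid$n_bins - 1L) * grid$dt
}

same_spacing <- function(a, b, rel_tol = 1e-9) {
  abs(a$dt - b$dt) <= rel_tol * a$dt
}

#' Time-resolved profile (photon-count histogram)
#'
#' A TRP is the histogram of photon arrival times recorded for one sample on
#' one occasion, with free-form metadata (sample id, storage day, condition).
#'
#' @param grid a [time_grid].
#' @param counts nonnegative counts per bin, length `grid$n_bins`, no NaN.
#' @param meta named list of labels (e.g. `sample_id`, `day`, `condition`).
#' @return An object of class `trp`.
#' @export
trp <- function(grid, counts, meta = list()) {
  stopifnot(inherits(grid, "time_grid"))
  if (length(counts) != grid$n_bins) stop("counts length must equal n_bins")
  if (any(!is.finite(counts))) stop("counts contain NaN/Inf")
  if (any(counts < 0)) stop("counts must be nonnegative")
  structure(list(grid = grid, counts = as.numeric(counts), meta = meta),
            class = "trp")
}

#' Instrument response function
#'
#' The recorded system response to an effectively instantaneous input, stored
#' normalized (weights sum to 1). Measured data are modelled as the true
#' time-resolved response convolved with this kernel.
#'
#' @param grid a [time_grid].
#' @param weights nonnegative weights per bin; renormalized to unit sum.
#' @return An object of class `instrument_response`.
#' @export
instrument_response <- function(grid, weights) {
  stopifnot(inherits(grid, "time_grid"))
  if (length(weights) != grid$n_bins) stop("weights length must equal n_bins")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and nonnegative")
  tot <- sum(weights)
  if (tot <= 0) stop("IRF weights are all zero")
  structure(list(grid = grid, weights = weights / tot),
            class = "instrument_response")
}

#' Gaussian instrument response
#'
#' Discretized Gaussian of a given full width at half maximum, renormalized to
#' unit sum; a synthetic stand-in for a measured IRF (streak-camera IRFs are
#' close to Gaussian at this time scale).
#'
#' @param grid a [time_grid].
#' @param fwhm full width at half maximum, ps (> 0). Default 159.83, a typical
#'   measured value for a picosecond-laser + streak-camera system.
#' @param center peak position, ps; must lie within the grid span.
#' @return An [instrument_response].
#' @export
make_gaussian_irf <- function(grid, fwhm = 159.83, center = 500) {
  stopifnot(inherits(grid, "time_grid"))
  if (fwhm <= 0) stop("fwhm must be positive")
  if (fwhm < 2 * grid$dt)
    warning("fwhm < 2*dt: IRF is under-resolved on this grid")
  times <- grid_times(grid)
  if (center < times[1L] || center > times[length(times)])
    stop("center must lie within the grid span")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  w <- exp(-(times - center)^2 / (2 * sigma^2))
  instrument_response(grid, w)
}

#' Convolve a model curve with an IRF
#'
#' Discrete causal convolution `y[k] = sum_j w[j] * f[k-j+1]` with the IRF's
#' normalized (dimensionless) weights, truncated to the model's grid length.
#' A delta IRF (single unit bin at the origin) is the identity; a delta at bin
#' k shifts the input by k bins; a unit-sum IRF preserves total signal mass up
#' to boundary truncation.
#'
#' @param model numeric flux values on `grid`.
#' @param irf an [instrument_response] with the same bin width as `grid`.
#' @param grid the [time_grid] both live on.
#' @return Numeric vector, same length as `model`.
#' @export
convolve_with_irf <- function(model, irf, grid) {
  stopifnot(inherits(irf, "instrument_response"), inherits(grid, "time_grid"))
  if (!same_spacing(grid, irf$grid)) stop("model and IRF grid spacings differ")
  n <- length(model)
  full <- convolve_direct(model, irf$weights)
  full[seq_len(n)]
}

# direct (summation) linear convolution, full length n+m-1; organized as a
# single matrix product so the 486-bin default grid stays fast in BLAS
convolve_direct <- function(x, w) {
  n <- length(x); m <- length(w)
  out <- numeric(n + m - 1L)
  nz <- which(w != 0)
  for (j in nz) out[j:(j + n - 1L)] <- out[j:(j + n - 1L)] + w[j] * x
  out
}

# convolution operator as a lower-triangular Toeplitz matrix, built once per
# inverse fit so each residual evaluation is a single matrix-vector product
irf_convolution_matrix <- function(irf, n) {
  w <- irf$weights
  M <- matrix(0, n, n)
  idx <- outer(seq_len(n), seq_len(n), "-") + 1L   # k - j + 1
  keep <- idx >= 1L & idx <= length(w)
  M[keep] <- w[idx[keep]]
  M
}

#' FWHM of an instrument response
#'
#' Full width at half maximum by linear interpolation of the first upward and
#' last downward crossings of half the peak value. Invariant to rescaling the
#' weights.
#'
#' @param irf an [instrument_response].
#' @return Width, ps.
#' @export
estimate_fwhm <- function(irf) {
  stopifnot(inherits(irf, "instrument_response"))
  w <- irf$weights
  pk <- max(w)
  if (pk <= 0) stop("flat IRF: FWHM undefined")
  half <- pk / 2
  times <- grid_times(irf$grid)
  above <- which(w >= half)
  if (length(above) == length(w))
    stop("IRF never falls below half maximum on the grid")
  i1 <- above[1L]; i2 <- above[length(above)]
  left <- if (i1 == 1L) times[1L] else {
    times[i1 - 1L] + (half - w[i1 - 1L]) / (w[i1] - w[i1 - 1L]) * irf$grid$dt
  }
  right <- if (i2 == length(w)) times[length(w)] else {
    times[i2] + (w[i2] - half) / (w[i2] - w[i2 + 1L]) * irf$grid$dt
  }
  right - left
}

#' Poisson photon-counting noise
#'
#' Rescales an expected curve to a target total and draws independent Poisson
#' counts per bin. Deterministic for a given seed.
#'
#' @param expected nonnegative expected flux per bin, not all zero.
#' @param total_counts target expected total number of photons (> 0).
#' @param rng_seed integer seed.
#' @return Integer-valued numeric vector of counts.
#' @export
simulate_counts <- function(expected, total_counts, rng_seed) {
  if (any(expected < 0)) stop("expected values must be nonnegative")
  tot <- sum(expected)
  if (tot <= 0) stop("expected curve is all zero")
  if (total_counts <= 0) stop("total_counts must be positive")
  lambda <- expected * (total_counts / tot)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(rng_seed))
  stats::rpois(length(lambda), lambda)
}
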