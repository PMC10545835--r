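# Smoothing, background handling and day-0 difference profiles applied to
# TRPs ahead of feature extraction.

#' Savitzky-Golay smoothing of a TRP
#'
#' Local least-squares polynomial smoothing (FIR filter). Interior bins use
#' the centered window; edge bins use the asymmetric least-squares fits on
#' the truncated window. With the defaults (order 2, frame 5) the interior
#' weights are (-3, 12, 17, 12, -3)/35.
#'
#' @param profile a [trp].
#' @param poly_order polynomial order (default 2).
#' @param frame_length odd window length, > `poly_order` (default 5).
#' @return A smoothed [trp] with the same grid and metadata.
#' @export
savitzky_golay_smooth <- function(profile, poly_order = 2L, frame_length = 5L) {
  stopifnot(inherits(profile, "trp"))
  if (frame_length %% 2L != 1L) stop("frame_length must be odd")
  if (frame_length <= poly_order) stop("frame_length must exceed poly_order")
  if (profile$grid$n_bins < frame_length)
    stop("profile shorter than the smoothing frame")
  sm <- signal::sgolayfilt(profile$counts, p = poly_order, n = frame_length)
  sm[sm < 0] <- 0   # counts cannot go negative through smoothing overshoot
  trp(profile$grid, sm, profile$meta)
}

#' Savitzky-Golay interior filter weights
#'
#' The centered-window convolution weights the smoother applies to interior
#' bins, i.e. the middle row of the local least-squares projection matrix.
#' For order 2, frame 5 these are (-3, 12, 17, 12, -3)/35.
#'
#' @inheritParams savitzky_golay_smooth
#' @return Numeric vector of length `frame_length`.
#' @export
sg_coefficients <- function(poly_order = 2L, frame_length = 5L) {
  if (frame_length %% 2L != 1L) stop("frame_length must be odd")
  if (frame_length <= poly_order) stop("frame_length must exceed poly_order")
  F <- signal::sgolay(p = poly_order, n = frame_length)
  as.numeric(F[(frame_length + 1L) %/% 2L, ])
}

#' Constant-background subtraction
#'
#' Subtracts the mean of a pre-pulse baseline window (dark counts) from every
#' bin, clamping at zero. Warns when the window mean exceeds half the peak,
#' i.e. when the window plausibly overlaps the pulse.
#'
#' @param profile a [trp].
#' @param baseline_window integer bin indices of the baseline region.
#' @return A background-free [trp].
#' @export
subtract_background <- function(profile, baseline_window) {
  stopifnot(inherits(profile, "trp"))
  if (any(baseline_window < 1L) || any(baseline_window > profile$grid$n_bins))
    stop("baseline_window out of range")
  bg <- mean(profile$counts[baseline_window])
  if (bg > 0.5 * max(profile$counts))
    warning("baseline window mean exceeds 50% of the peak: window may overlap the pulse")
  trp(profile$grid, pmax(profile$counts - bg, 0), profile$meta)
}

#' Day-0 difference profile
#'
#' Elementwise day-d minus day-0 counts for the same sample, the
#' initial-quality correction applied before PCA: each fruit's later profiles
#' are expressed relative to its own day-0 profile. The result carries the
#' day-d metadata and may be negative.
#'
#' @param profile_day_d the later-day [trp].
#' @param profile_day_0 the day-0 [trp] of the same sample.
#' @return An object of class `difference_profile` with fields `grid`,
#'   `delta_counts` and `meta`.
#' @export
difference_profile <- function(profile_day_d, profile_day_0) {
  stopifnot(inherits(profile_day_d, "trp"), inherits(profile_day_0, "trp"))
  ga <- profile_day_d$grid; gb <- profile_day_0$grid
  if (ga$n_bins != gb$n_bins || !same_spacing(ga, gb) ||
      abs(ga$t0 - gb$t0) > 1e-9 * ga$dt)
    stop("difference_profile: grids differ")
  ida <- profile_day_d$meta$sample_id; idb <- profile_day_0$meta$sample_id
  if (!is.null(ida) && !is.null(idb) && !identical(ida, idb))
    stop("difference_profile: sample ids differ")
  structure(list(grid = ga,
                 delta_counts = profile_day_d$counts - profile_day_0$counts,
                 meta = profile_day_d$meta),
            class = "difference_profile")
}
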