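# Closed-form time-domain transmittance of a homogeneous turbid slab under the
# diffusion approximation, with extrapolated-boundary dipole image sources.
# Internal units are fixed throughout the package: mm, ps, mm^-1.

#' Speed of light in vacuum
#'
#' Named constant used by all diffusion-time computations, in mm/ps.
#' @export
C_VACUUM_MM_PS <- 0.299792458

#' Optical properties of a turbid medium
#'
#' Bundles the absorption coefficient \eqn{\mu_a} and the reduced scattering
#' coefficient \eqn{\mu_s'} (both mm\eqn{^{-1}}) that the time-resolved
#' transmittance model and the inverse fit operate on.
#'
#' @param mu_a absorption coefficient, mm^-1; must be > 0.
#' @param mu_s_prime reduced scattering coefficient, mm^-1; must be > 0.
#'   The diffusion approximation assumes scattering dominates absorption;
#'   a warning (not an error) is raised when `mu_s_prime <= mu_a`.
#' @return An object of class `optical_properties`.
#' @examples
#' optical_properties(mu_a = 0.01, mu_s_prime = 0.6)
#' @export
optical_properties <- function(mu_a, mu_s_prime) {
  stopifnot(is.numeric(mu_a), length(mu_a) == 1L, is.finite(mu_a),
            is.numeric(mu_s_prime), length(mu_s_prime) == 1L, is.finite(mu_s_prime))
  if (mu_a <= 0) stop("mu_a must be positive")
  if (mu_s_prime <= 0) stop("mu_s_prime must be positive")
  if (mu_s_prime <= mu_a)
    warning("mu_s_prime <= mu_a: outside the diffusion regime the slab solution assumes")
  structure(list(mu_a = mu_a, mu_s_prime = mu_s_prime),
            class = "optical_properties")
}

#' Slab geometry and boundary parameters
#'
#' Geometry of the transmittance measurement: slab thickness `s` (the fruit
#' diameter along the optical axis), lateral source-detector offset `rho`
#' (0 for on-axis transmittance), tissue refractive index `n`, the internal
#' reflection parameter `A` entering the extrapolation length, and the dipole
#' truncation order for the image-source sum.
#'
#' @param thickness_s slab thickness, mm.
#' @param rho lateral detector offset from the injection axis, mm. Default 0.
#' @param refractive_index_n refractive index of the medium (>= 1). Default 1.34.
#' @param boundary_A internal-reflection boundary parameter (> 0). Default 2.58.
#' @param dipole_max_m image sources are summed for |m| <= `dipole_max_m`;
#'   the default 3 uses seven dipoles (m = 0, +/-1, +/-2, +/-3).
#' @return An object of class `slab_geometry`.
#' @examples
#' slab_geometry(thickness_s = 51)
#' @export
slab_geometry <- function(thickness_s, rho = 0, refractive_index_n = 1.34,
                          boundary_A = 2.58, dipole_max_m = 3L) {
  stopifnot(is.numeric(thickness_s), length(thickness_s) == 1L, is.finite(thickness_s))
  if (thickness_s <= 0) stop("thickness_s must be positive")
  if (rho < 0) stop("rho must be nonnegative")
  if (refractive_index_n < 1) stop("refractive_index_n must be >= 1")
  if (boundary_A <= 0) stop("boundary_A must be positive")
  dipole_max_m <- as.integer(dipole_max_m)
  if (dipole_max_m < 0) stop("dipole_max_m must be a nonnegative integer")
  structure(list(thickness_s = thickness_s, rho = rho,
                 refractive_index_n = refractive_index_n,
                 boundary_A = boundary_A, dipole_max_m = dipole_max_m),
            class = "slab_geometry")
}

#' Derived diffusion quantities
#'
#' Computes the quantities the slab solution is written in terms of: the light
#' speed in the medium `v = c/n` (mm/ps), the diffusion length
#' `D = 1/(3 mu_s')` (mm), the isotropic source depth `z0 = 1/mu_s'` (mm) and
#' the extrapolation length `ze = 2 A D` (mm). `D` follows the
#' absorption-independent convention (scattering only).
#'
#' @param props an [optical_properties] object.
#' @param geom a [slab_geometry] object.
#' @return A list with fields `v`, `D`, `z0`, `ze`, all positive.
#' @examples
#' derived_quantities(optical_properties(0.01, 0.5), slab_geometry(50))
#' @export
derived_quantities <- function(props, geom) {
  stopifnot(inherits(props, "optical_properties"), inherits(geom, "slab_geometry"))
  mu_s <- props$mu_s_prime
  if (mu_s <= 0) stop("mu_s_prime must be positive")
  D <- 1 / (3 * mu_s)
  list(v = C_VACUUM_MM_PS / geom$refractive_index_n,
       D = D,
       z0 = 1 / mu_s,
       ze = 2 * geom$boundary_A * D)
}

#' Image-source depths for one dipole order
#'
#' Positions of the positive and negative image sources of dipole order `m`
#' for the extrapolated-boundary slab:
#' `Z1m = s(1 - 2m) - 4m ze - z0` and `Z2m = s(1 - 2m) - (4m - 2) ze + z0`.
#'
#' @param m dipole order (vectorized); |m| must not exceed `geom$dipole_max_m`.
#' @param geom a [slab_geometry] object.
#' @param derived result of [derived_quantities()].
#' @return A list with numeric fields `Z1` and `Z2` (mm), same length as `m`.
#' @export
image_source_positions <- function(m, geom, derived) {
  stopifnot(inherits(geom, "slab_geometry"))
  if (any(abs(m) > geom$dipole_max_m))
    stop("|m| exceeds dipole_max_m of the geometry")
  s <- geom$thickness_s
  list(Z1 = s * (1 - 2 * m) - 4 * m * derived$ze - derived$z0,
       Z2 = s * (1 - 2 * m) - (4 * m - 2) * derived$ze + derived$z0)
}

#' Time-resolved slab transmittance
#'
#' Photon flux per unit area per unit time emerging from the far face of a
#' homogeneous slab, evaluated on a grid of arrival times. The dipole
#' image-source sum is truncated at `|m| <= geom$dipole_max_m`. The returned
#' value is the nonnegative magnitude of the dipole sum times the common
#' exponential prefactor; the solution's overall sign is a convention artifact
#' and physical flux is nonnegative. Times `t <= 0` map to exactly 0 (no
#' photon can traverse the slab in nonpositive time; the `t^{5/2}` pole is
#' never touched).
#'
#' @param t_grid numeric vector of times, ps, sorted ascending.
#' @param props an [optical_properties] object.
#' @param geom a [slab_geometry] object.
#' @return Numeric vector of nonnegative flux values (mm^-2 ps^-1 up to the
#'   source strength), one per time.
#' @examples
#' g <- slab_geometry(50)
#' p <- optical_properties(0.01, 0.5)
#' transmittance_curve(c(500, 1000, 2000), p, g)
#' @export
transmittance_curve <- function(t_grid, props, geom) {
  stopifnot(inherits(props, "optical_properties"), inherits(geom, "slab_geometry"))
  if (length(t_grid) == 0L) stop("empty time grid")
  if (is.unsorted(t_grid)) stop("t_grid must be sorted ascending")
  out <- numeric(length(t_grid))
  pos <- t_grid > 0
  if (!any(pos)) return(out)
  t <- t_grid[pos]
  d <- derived_quantities(props, geom)
  m <- seq.int(-geom$dipole_max_m, geom$dipole_max_m)
  zz <- image_source_positions(m, geom, d)
  fourDvt <- 4 * d$D * d$v * t                      # mm^2
  # common exponential prefactor factored out of the dipole sum
  pref <- exp(-props$mu_a * d$v * t - geom$rho^2 / fourDvt) /
    (2 * (4 * pi * d$D * d$v)^1.5 * t^2.5)
  inv <- -1 / fourDvt                               # length(t)
  dip <- exp(outer(inv, zz$Z1^2)) %*% zz$Z1 - exp(outer(inv, zz$Z2^2)) %*% zz$Z2
  val <- abs(pref * as.vector(dip))
  if (any(!is.finite(val))) stop("non-finite transmittance value (numerical failure)")
  out[pos] <- val
  out
}

#' Mean time of flight of a time-resolved profile
#'
#' First moment of the curve on its grid, \eqn{\sum t f / \sum f}. Diagnostic
#' for the scattering-induced delay: for fixed absorption and geometry the
#' mean time of flight increases strictly with the reduced scattering
#' coefficient.
#'
#' @param curve nonnegative flux or count values.
#' @param t_grid times, ps, same length as `curve`.
#' @return Mean arrival time, ps.
#' @export
mean_time_of_flight <- function(curve, t_grid) {
  stopifnot(length(curve) == length(t_grid))
  if (any(curve < 0)) stop("curve must be nonnegative")
  tot <- sum(curve)
  if (tot <= 0) stop("curve is all zero: mean time of flight undefined")
  sum(t_grid * curve) / tot
}
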