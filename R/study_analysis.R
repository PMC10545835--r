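# Phenotype color indexes, per-sample storage-time correlations, and the
# per-study correlation table.

#' Chroma of a CIELAB color
#'
#' `sqrt(a*^2 + b*^2)`, the chromatic intensity of the skin color.
#' @param a_star,b_star CIELAB a* and b* values (vectorized).
#' @return Chroma value(s).
#' @examples chroma(3, 4)  # 5
#' @export
chroma <- function(a_star, b_star) sqrt(a_star^2 + b_star^2)

#' Hue angle of a CIELAB color
#'
#' Single-argument arctangent of the ratio b*/a*, in degrees, range
#' (-90, 90). This is the ratio convention common in fruit colorimetry, not
#' the quadrant-resolved two-argument form: for a* < 0 the two conventions
#' differ by 180 degrees.
#'
#' @param a_star,b_star CIELAB a* and b* values (vectorized); `a_star` must
#'   be nonzero.
#' @return Hue angle(s), degrees.
#' @examples hue(1, 1)  # 45
#' @export
hue <- function(a_star, b_star) {
  if (any(a_star == 0)) stop("hue undefined for a* = 0 under the ratio convention")
  atan(b_star / a_star) * 180 / pi
}

#' a*/b* color ratio
#' @param a_star,b_star CIELAB values (vectorized); `b_star` must be nonzero.
#' @return a*/b*.
#' @export
ab_ratio <- function(a_star, b_star) {
  if (any(b_star == 0)) stop("a*/b* undefined for b* = 0")
  a_star / b_star
}

#' Pearson correlation with storage time
#'
#' Product-moment correlation of a measured parameter with storage day for
#' one sample's repeated measurements.
#'
#' @param days storage days (>= 3 paired observations).
#' @param measurements parameter values, same length.
#' @return Pearson r.
#' @export
correlate_with_time <- function(days, measurements) {
  if (length(days) != length(measurements)) stop("length mismatch")
  keep <- is.finite(days) & is.finite(measurements)
  days <- days[keep]; measurements <- measurements[keep]
  if (length(days) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(days) == 0 || stats::sd(measurements) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(days, measurements)
}

# correlation that reports degenerate columns as NA instead of erroring
cor_or_na <- function(days, x) {
  keep <- is.finite(days) & is.finite(x)
  if (sum(keep) < 3L || stats::sd(x[keep]) == 0 || stats::sd(days[keep]) == 0)
    return(NA_real_)
  stats::cor(days[keep], x[keep])
}

#' Per-sample correlation table for one storage condition
#'
#' One row per sample; columns are the Pearson correlations of each
#' parameter with storage day: skin color (L*, a*, b*, a*/b*, Chroma, Hue),
#' the fitted optical properties (mu_s', mu_a) and the PC1 score of the
#' day-0 difference spectra. Degenerate (zero-variance or incomplete)
#' cells are reported as NA, never as 0.
#'
#' @param study a `study_dataset`.
#' @param fits data.frame from [fit_study()] (columns `sample_id`, `day`,
#'   `mu_a`, `mu_s_prime`), or NULL to omit the optical columns.
#' @param pc1_scores optional data.frame with `sample_id`, `day`, `pc1`.
#' @param condition storage condition to tabulate.
#' @return data.frame with one row per sample and columns `sample_id`,
#'   `L_star`, `a_star`, `b_star`, `ab_ratio`, `chroma`, `hue`,
#'   `mu_s_prime`, `mu_a`, `pc1_score`.
#' @export
build_correlation_table <- function(study, fits = NULL, pc1_scores = NULL,
                                    condition = "shelf") {
  stopifnot(inherits(study, "study_dataset"))
  recs <- study$records[study$records$condition == condition, , drop = FALSE]
  ids <- unique(recs$sample_id)
  rows <- lapply(ids, function(sid) {
    r <- recs[recs$sample_id == sid, , drop = FALSE]
    r <- r[order(r$day), , drop = FALSE]
    d <- r$day
    ft <- if (!is.null(fits)) {
      f <- fits[fits$sample_id == sid, , drop = FALSE]
      f[order(f$day), , drop = FALSE]
    } else NULL
    pc <- if (!is.null(pc1_scores)) {
      p <- pc1_scores[pc1_scores$sample_id == sid, , drop = FALSE]
      p[order(p$day), , drop = FALSE]
    } else NULL
    data.frame(
      sample_id = sid,
      L_star = cor_or_na(d, r$L_star),
      a_star = cor_or_na(d, r$a_star),
      b_star = cor_or_na(d, r$b_star),
      ab_ratio = cor_or_na(d, ab_ratio(r$a_star, r$b_star)),
      chroma = cor_or_na(d, chroma(r$a_star, r$b_star)),
      hue = cor_or_na(d, hue(r$a_star, r$b_star)),
      mu_s_prime = if (is.null(ft)) NA_real_ else cor_or_na(ft$day, ft$mu_s_prime),
      mu_a = if (is.null(ft)) NA_real_ else cor_or_na(ft$day, ft$mu_a),
      pc1_score = if (is.null(pc)) NA_real_ else cor_or_na(pc$day, pc$pc1))
  })
  do.call(rbind, rows)
}

#' Bundled reference optical-property tables
#'
#' Fitted (mu_a, mu_s') values for ten kiwifruit followed through a
#' shelf-life storage series (days 0, 1, 3, ..., 13) and ten through a cold
#' storage series (days 0, 7, ..., 49), as tabulated in a published storage
#' experiment with a picosecond transmittance system. Useful as realistic
#' anchor values and for recomputing storage-time correlations from printed
#' data.
#'
#' @param condition "shelf" or "cold".
#' @return data.frame with columns `sample_id`, `day`, `mu_a`, `mu_s_prime`.
#' @export
reference_optical_table <- function(condition = c("shelf", "cold")) {
  condition <- match.arg(condition)
  path <- system.file("extdata",
                      paste0("reference_optical_", condition, ".csv"),
                      package = "kiwitrts", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
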