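# Readers and writers for the shared two-column CSV dialect and study
# fixture directories.

#' Write a time/counts curve as CSV
#'
#' Two columns `time_ps,counts`, header required, "." decimal separator —
#' the dialect shared by TRPs and IRFs.
#'
#' @param time_ps numeric times, ps.
#' @param counts values per bin.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trp_csv <- function(time_ps, counts, path) {
  stopifnot(length(time_ps) == length(counts))
  utils::write.csv(data.frame(time_ps = time_ps, counts = counts),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TRP (or IRF) CSV
#'
#' Validates the header, uniform grid spacing (relative 1e-6) and
#' nonnegative counts; the offending row is named on failure.
#'
#' @param path CSV file with columns `time_ps,counts`.
#' @param meta optional metadata list attached to the profile.
#' @return A [trp].
#' @export
read_trp_csv <- function(path, meta = list()) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path)
  if (!all(c("time_ps", "counts") %in% names(df)))
    stop("missing header 'time_ps,counts' in ", path)
  tt <- df$time_ps
  if (length(tt) < 8L) stop("fewer than 8 rows in ", path)
  dts <- diff(tt)
  dt <- dts[1L]
  if (dt <= 0 || any(abs(dts - dt) > 1e-6 * dt)) {
    bad <- which(abs(dts - dt) > 1e-6 * dt)[1L]
    stop("non-uniform time grid in ", path, " near row ", bad + 1L)
  }
  if (any(df$counts < 0)) {
    stop("negative count in ", path, " at row ", which(df$counts < 0)[1L])
  }
  trp(time_grid(tt[1L], dt, length(tt)), df$counts, meta)
}

#' Read a study fixture directory
#'
#' Inverse of [write_fixture()]: loads `manifest.csv`, `irf.csv`, the
#' per-profile CSVs and (when present) `truth.csv`.
#'
#' @param directory fixture directory.
#' @return A `study_dataset` (without a generator config; `truth` is NULL
#'   when the fixture omits it).
#' @export
read_study_fixture <- function(directory) {
  mpath <- file.path(directory, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", directory)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  irf_trp <- read_trp_csv(file.path(directory, "irf.csv"))
  irf <- instrument_response(irf_trp$grid, irf_trp$counts)
  trps <- list()
  for (i in seq_len(nrow(manifest))) {
    p <- file.path(directory, manifest$trp_path[i])
    if (!file.exists(p))
      stop("manifest references missing TRP for sample ",
           manifest$sample_id[i], " day ", manifest$day[i], ": ", p)
    key <- trp_key(manifest$sample_id[i], manifest$day[i])
    trps[[key]] <- read_trp_csv(p, list(sample_id = manifest$sample_id[i],
                                        day = manifest$day[i],
                                        condition = manifest$condition[i]))
  }
  tpath <- file.path(directory, "truth.csv")
  truth <- if (file.exists(tpath)) utils::read.csv(tpath, stringsAsFactors = FALSE) else NULL
  records <- manifest[, setdiff(names(manifest), "trp_path"), drop = FALSE]
  structure(list(records = records, trps = trps, irf = irf, truth = truth,
                 config = NULL),
            class = "study_dataset")
}
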