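# PCA on TRP difference spectra, firmness-based softening classes, and
# cross-validated SVM staging.

#' PCA of difference spectra
#'
#' Column-mean-centered principal component decomposition (no variance
#' scaling: all bins share count units). Each loading's sign is fixed so its
#' largest-magnitude element is positive, making component orientation
#' reproducible. Scores are recoverable as `(row - mean) %*% t(loadings)`.
#'
#' @param x numeric matrix, profiles in rows, time bins in columns; >= 2 rows,
#'   finite entries.
#' @param n_components number of components to keep (default: all).
#' @return An object of class `pca_model`: `mean_vector`, `loadings`
#'   (components x bins, orthonormal rows), `explained_variance_ratio`,
#'   `scores` (rows x components).
#' @export
fit_pca <- function(x, n_components = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA needs at least 2 rows")
  if (any(!is.finite(x))) stop("PCA input contains non-finite entries")
  k_max <- min(nrow(x) - 1L, ncol(x))
  if (is.null(n_components)) n_components <- k_max
  if (n_components > k_max)
    stop("fewer usable components than requested (", k_max, " available)")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- n_components
  load <- t(pc$rotation[, seq_len(k), drop = FALSE])      # k x bins
  flip <- apply(load, 1L, function(r) sign(r[which.max(abs(r))]))
  flip[flip == 0] <- 1
  load <- load * flip
  scores <- pc$x[, seq_len(k), drop = FALSE] * rep(flip, each = nrow(x))
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(mean_vector = pc$center,
                 loadings = load,
                 explained_variance_ratio = evr[seq_len(k)],
                 scores = unname(scores)),
            class = "pca_model")
}

#' Project new rows onto a fitted PCA
#' @param pca a `pca_model`.
#' @param x matrix of rows on the same bins.
#' @return Score matrix, rows x components.
#' @export
pca_transform <- function(pca, x) {
  x <- as.matrix(x)
  sweep(x, 2L, pca$mean_vector) %*% t(pca$loadings)
}

#' Firmness-based softening classes
#'
#' Rank-based equal-count classes of measured firmness: class 1 holds the
#' firmest fruit (early softening), the last class the softest (late
#' softening). Ties are broken by stable input order; when class counts
#' cannot be exactly equal the earlier classes receive the extra samples.
#'
#' @param firmness numeric firmness values, N/cm^2.
#' @param n_classes number of stages (default 3: early/mid/late).
#' @return Integer labels in `1:n_classes`, 1 = firmest.
#' @export
assign_softening_classes <- function(firmness, n_classes = 3L) {
  n <- length(firmness)
  n_classes <- as.integer(n_classes)
  if (n_classes > n) stop("more classes than samples")
  if (length(unique(firmness)) == 1L)
    warning("all firmness values equal: class labels follow input order only")
  ord <- order(-firmness)            # stable: ties keep input order
  sizes <- rep(n %/% n_classes, n_classes)
  extra <- n %% n_classes
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- integer(n)
  labels[ord] <- rep(seq_len(n_classes), times = sizes)
  labels
}

#' Select discriminative principal components
#'
#' Ranks the first `n_candidates` components by the between-class to
#' within-class variance ratio of their scores (a per-component Fisher
#' criterion) and returns the best `k`. An explicit `override` index vector
#' is honored verbatim, for reproducing a fixed published choice of
#' components.
#'
#' @param pca a `pca_model`.
#' @param scores score matrix (default the model's own training scores).
#' @param labels class labels, one per score row.
#' @param k number of components to select (default 3).
#' @param n_candidates how many leading components to consider (default 10).
#' @param override explicit component indices; returned unchanged when given.
#' @return Integer component indices, ordered by decreasing discriminability.
#' @export
select_components <- function(pca, scores = pca$scores, labels, k = 3L,
                              n_candidates = 10L, override = NULL) {
  if (!is.null(override)) {
    if (max(override) > ncol(scores)) stop("override index out of range")
    return(as.integer(override))
  }
  n_candidates <- min(n_candidates, ncol(scores))
  if (k > n_candidates) stop("k exceeds the number of candidate components")
  labels <- as.factor(labels)
  ratio <- vapply(seq_len(n_candidates), function(j) {
    s <- scores[, j]
    mu <- mean(s)
    within <- sum(tapply(s, labels, function(v) sum((v - mean(v))^2)))
    between <- sum(tapply(s, labels, function(v) length(v) * (mean(v) - mu)^2))
    if (within <= .Machine$double.eps * sum((s - mu)^2)) Inf else between / within
  }, numeric(1))
  if (all(!is.finite(ratio))) {
    warning("degenerate within-class variance everywhere: falling back to variance order")
    return(seq_len(k))
  }
  order(ratio, decreasing = TRUE)[seq_len(k)]
}

#' SVM staging with stratified cross-validation
#'
#' Trains a support vector machine (linear kernel by default, one-vs-one
#' multiclass) on the selected component scores under stratified k-fold
#' cross-validation, features standardized per training fold. Reports the
#' pooled out-of-fold confusion matrix (rows = predicted, columns = actual)
#' and its accuracy, trace/total.
#'
#' @param scores numeric feature matrix (rows = samples).
#' @param labels class labels.
#' @param folds number of cross-validation folds (default 5).
#' @param seed integer seed fixing the fold assignment.
#' @param kernel SVM kernel (default "linear").
#' @param cost regularization constant (default 1).
#' @return An object of class `staging_report`: `confusion_matrix`,
#'   `fold_accuracies`, `overall_accuracy`, `folds`, `seed`.
#' @export
train_classify_svm <- function(scores, labels, folds = 5L, seed = 1L,
                               kernel = "linear", cost = 1) {
  scores <- as.matrix(scores)
  if (any(!is.finite(scores))) stop("non-finite feature values")
  labels <- as.factor(labels)
  n <- nrow(scores)
  stopifnot(length(labels) == n)
  lev <- levels(labels)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  # stratified fold assignment: shuffle within class, deal out round-robin
  fold_id <- integer(n)
  for (cl in lev) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }

  pred <- factor(rep(NA_character_, n), levels = lev)
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    tr_labels <- droplevels(labels[tr])
    if (nlevels(tr_labels) < length(lev)) {
      missing_cl <- setdiff(lev, levels(tr_labels))
      stop("class ", paste(missing_cl, collapse = ", "),
           " absent from training folds; use fewer folds or more samples")
    }
    mu <- colMeans(scores[tr, , drop = FALSE])
    sd_ <- apply(scores[tr, , drop = FALSE], 2L, stats::sd)
    sd_[sd_ == 0] <- 1
    std <- function(m) sweep(sweep(m, 2L, mu), 2L, sd_, "/")
    fit <- e1071::svm(x = std(scores[tr, , drop = FALSE]), y = labels[tr],
                      kernel = kernel, cost = cost, scale = FALSE)
    p <- stats::predict(fit, std(scores[te, , drop = FALSE]))
    pred[te] <- p
    fold_acc[f] <- mean(p == labels[te])
  }

  cm <- table(predicted = pred, actual = labels)
  structure(list(confusion_matrix = unclass(cm),
                 fold_accuracies = fold_acc,
                 overall_accuracy = sum(diag(cm)) / n,
                 folds = folds, seed = as.integer(seed)),
            class = "staging_report")
}

#' Full staging analysis of one storage condition
#'
#' Builds day-0 difference spectra for every record of the condition, fits
#' the PCA, assigns firmness tertile stages, selects discriminative
#' components and runs the cross-validated SVM.
#'
#' @param study a `study_dataset`.
#' @param condition which storage condition to stage ("shelf" or "cold").
#' @param k number of components fed to the SVM (default 3).
#' @param folds,seed cross-validation settings.
#' @param components optional explicit component indices.
#' @return A list: `pca`, `labels`, `selected_components`, `report`
#'   (a `staging_report`), `class_thresholds` (firmness cut values, N/cm^2).
#' @export
stage_condition <- function(study, condition, k = 3L, folds = 5L, seed = 1L,
                            components = NULL) {
  stopifnot(inherits(study, "study_dataset"))
  recs <- study$records[study$records$condition == condition, , drop = FALSE]
  if (nrow(recs) == 0L) stop("no records for condition ", condition)
  diffs <- difference_matrix(study, condition)
  pca <- fit_pca(diffs)
  labels <- assign_softening_classes(recs$firmness_N_cm2, 3L)
  sel <- select_components(pca, labels = labels, k = k, override = components)
  report <- train_classify_svm(pca$scores[, sel, drop = FALSE], labels,
                               folds = folds, seed = seed)
  thr <- sort(tapply(recs$firmness_N_cm2, labels, min), decreasing = TRUE)
  list(pca = pca, labels = labels, selected_components = sel,
       report = report, class_thresholds = as.numeric(thr))
}

#' Matrix of day-0 difference spectra for one condition
#'
#' One row per (sample, day) record, ordered as the study records; each row
#' is that sample's TRP minus its own day-0 TRP (day-0 rows are zero).
#'
#' @param study a `study_dataset`.
#' @param condition storage condition to extract.
#' @return Numeric matrix, records x bins.
#' @export
difference_matrix <- function(study, condition) {
  recs <- study$records[study$records$condition == condition, , drop = FALSE]
  n_bins <- study$irf$grid$n_bins
  out <- matrix(0, nrow(recs), n_bins)
  for (i in seq_len(nrow(recs))) {
    sid <- recs$sample_id[i]
    d <- study$trps[[trp_key(sid, recs$day[i])]]
    d0 <- study$trps[[trp_key(sid, 0)]]
    if (is.null(d) || is.null(d0)) stop("missing TRP for sample ", sid)
    out[i, ] <- difference_profile(d, d0)$delta_counts
  }
  out
}
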