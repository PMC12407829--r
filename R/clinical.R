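#' Negative-deviation outlier mask
#'
#' Marks deviation scores below the outlier threshold, `z < -1.96` by default
#' (the bottom 2.5% of the normative range; strict inequality, so exactly
#' -1.96 is not an outlier). Only negative deviations count — the clinical
#' readouts target atrophy. Missing z propagate as non-outliers; the number
#' of missing entries is attached as attribute `"n_missing"`.
#'
#' @param z deviation matrix (subjects x ROIs).
#' @param threshold outlier threshold.
#' @return logical matrix of the same shape.
#' @export
outlier_mask <- function(z, threshold = -1.96) {
  m <- z < threshold
  nmiss <- sum(is.na(m))
  if (nmiss > 0) m[is.na(m)] <- FALSE
  attr(m, "n_missing") <- nmiss
  m
}

#' Total outlier count (tOC) per subject
#'
#' Number of ROIs in which a subject's deviation score is below the
#' threshold. Under a calibrated model with R ROIs the HC expectation is
#' `R * pnorm(-1.96)` (~4.2 outliers at 167 ROIs).
#'
#' @inheritParams outlier_mask
#' @return named integer vector, one count per subject.
#' @export
toc <- function(z, threshold = -1.96) {
  rowSums(outlier_mask(z, threshold))
}

#' Outlier percentage per ROI and group
#'
#' 100 x the within-group column means of the outlier mask. Empty groups are
#' omitted with a warning.
#'
#' @inheritParams outlier_mask
#' @param groups group labels (`"HC"` / `"AD"`), aligned with rows of `z`.
#' @return long data frame `roi`, `group`, `pct_outliers`.
#' @export
outlier_percentages <- function(z, groups, threshold = -1.96) {
  stopifnot(length(groups) == nrow(z))
  m <- outlier_mask(z, threshold)
  out <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (!length(idx)) { warning("empty group: ", g); next }
    out[[g]] <- data.frame(
      roi = colnames(z) %||% paste0("roi_", seq_len(ncol(z))),
      group = g,
      pct_outliers = 100 * colMeans(m[idx, , drop = FALSE]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' HC-vs-AD classification from deviation scores
#'
#' Linear-kernel support vector classifier on ROI-level z-scores with
#' stratified k-fold cross-validation; features are standardized with
#' training-fold statistics; returns the fold-mean ROC-AUC. Subjects with
#' any missing feature are dropped. If the smaller class has fewer members
#' than folds, the fold count is reduced with a warning.
#'
#' @param z deviation matrix (subjects x ROIs).
#' @param labels diagnosis labels, `"HC"`/`"AD"`, aligned with rows.
#' @param folds number of cross-validation folds (default 10).
#' @param seed integer seed (fold assignment).
#' @param kernel `"linear"` (default) or `"radial"`.
#' @param cost SVM regularization constant.
#' @return list with `mean_auc` and the per-fold `fold_auc`.
#' @export
classify_groups <- function(z, labels, folds = 10L, seed = 1L,
                            kernel = c("linear", "radial"), cost = 1) {
  kernel <- match.arg(kernel)
  stopifnot(length(labels) == nrow(z))
  keep <- stats::complete.cases(z)
  z <- as.matrix(z)[keep, , drop = FALSE]
  labels <- labels[keep]
  cls <- sort(unique(labels))
  if (length(cls) < 2) stop("both classes must be present", call. = FALSE)
  y <- factor(labels, levels = c("HC", "AD"))
  minc <- min(table(y))
  if (minc < folds) {
    folds <- max(2L, minc)
    warning("class smaller than fold count; using ", folds, " folds")
  }
  fold_of <- integer(length(y))
  with_seed(seed, {
    for (lv in levels(y)) {
      idx <- which(y == lv)
      fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold_auc <- vapply(seq_len(folds), function(f) {
    tr <- fold_of != f
    ctr <- colMeans(z[tr, , drop = FALSE])
    scl <- apply(z[tr, , drop = FALSE], 2, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    ztr <- sweep(sweep(z[tr, , drop = FALSE], 2, ctr), 2, scl, "/")
    zte <- sweep(sweep(z[!tr, , drop = FALSE], 2, ctr), 2, scl, "/")
    fit <- e1071::svm(ztr, y[tr], kernel = kernel, cost = cost,
                      scale = FALSE, probability = FALSE)
    dvm <- attr(stats::predict(fit, zte, decision.values = TRUE),
                "decision.values")
    # libsvm orients decision values toward the first label it saw in
    # training; the column name ("A/B" = positive favors A) disambiguates
    dv <- if (startsWith(colnames(dvm)[1], "AD")) dvm[, 1] else -dvm[, 1]
    yte <- y[!tr]
    if (length(unique(yte)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(response = yte, predictor = dv,
                                   levels = c("HC", "AD"), quiet = TRUE,
                                   direction = "<")))
  }, numeric(1))
  list(mean_auc = mean(fold_auc, na.rm = TRUE), fold_auc = fold_auc)
}
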