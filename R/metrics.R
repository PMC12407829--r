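#' Mean standardized log loss (MSLL)
#'
#' Mean over test points of the model's negative log predictive density minus
#' that of the trivial predictor — a Gaussian with the mean and variance of
#' the warped training responses. Both densities are evaluated on the warped
#' scale, so the warp Jacobian cancels. Negative values mean the model beats
#' the trivial predictor; a model identical to it scores exactly 0.
#'
#' @param mu_warped,total_sd warped-space predictive means and SDs.
#' @param w_test warped test responses (same scale as `mu_warped`).
#' @param train_ref list with `mean` and `var` of the warped training
#'   responses (stored by [wblr()] as `$train_ref`).
#' @return a single number (lower is better).
#' @export
msll <- function(mu_warped, total_sd, w_test, train_ref) {
  if (!is.finite(train_ref$var) || train_ref$var <= 0)
    stop("zero training variance; trivial predictor undefined", call. = FALSE)
  stopifnot(length(mu_warped) == length(w_test))
  nll_model <- 0.5 * log(2 * pi * total_sd^2) +
    (w_test - mu_warped)^2 / (2 * total_sd^2)
  nll_trivial <- 0.5 * log(2 * pi * train_ref$var) +
    (w_test - train_ref$mean)^2 / (2 * train_ref$var)
  mean(nll_model - nll_trivial)
}

#' Standardized mean squared error (SMSE)
#'
#' `mean((y - yhat)^2) / var(y)`; predicting the test mean scores ~1,
#' perfect predictions score 0. Unbiased (n-1) variance convention.
#'
#' @param yhat point predictions (original units).
#' @param y observed test responses.
#' @return a single non-negative number.
#' @export
smse <- function(yhat, y) {
  stopifnot(length(yhat) == length(y))
  v <- stats::var(y)
  if (!is.finite(v) || v <= 0)
    stop("constant test responses; SMSE undefined", call. = FALSE)
  mean((y - yhat)^2) / v
}

#' Explained variance and Pearson correlation
#'
#' `EV = 1 - var(y - yhat) / var(y)`; `rho` is the Pearson correlation of
#' predictions and observations. Both are invariant to adding a constant to
#' all predictions (which is why they are unchanged by mean-level transfer
#' adaptation). Constant predictions make `rho` undefined; `NA` is returned
#' with a warning.
#'
#' @inheritParams smse
#' @return a single number (`EV <= 1`; `rho` in `[-1, 1]` or `NA`).
#' @export
explained_variance <- function(yhat, y) {
  stopifnot(length(yhat) == length(y))
  v <- stats::var(y)
  if (!is.finite(v) || v <= 0)
    stop("constant test responses; EV undefined", call. = FALSE)
  1 - stats::var(y - yhat) / v
}

#' @rdname explained_variance
#' @export
pearson_rho <- function(yhat, y) {
  stopifnot(length(yhat) == length(y))
  if (stats::sd(yhat) == 0 || stats::sd(y) == 0) {
    warning("constant vector; correlation undefined")
    return(NA_real_)
  }
  stats::cor(yhat, y)
}

#' Model-fit metrics for one fitted model on a test set
#'
#' Computes MSLL, SMSE, EV and rho of a [wblr()] fit on (HC) test subjects.
#' All four are evaluated on the warped (Gaussianized) scale where the
#' likelihood lives — predictions \eqn{\mu_*} against warped responses
#' \eqn{W(\tilde y)}. This is also what makes EV and rho exactly invariant
#' under mean-level transfer adaptation: a constant warped-space offset
#' shifts \eqn{\mu_*} without touching spread or ranks.
#'
#' @param model fitted `wblr`.
#' @param test test cohort containing the model's ROI column.
#' @return one-row data frame `msll`, `smse`, `ev`, `rho`, `converged`.
#' @export
fit_metrics <- function(model, test) {
  pr <- predict(model, test)
  y <- test[[model$roi]]
  ystd <- (y - model$y_center) / model$y_scale
  w <- shash_warp(ystd, model$warp[["a"]], model$warp[["b"]])
  data.frame(
    msll = msll(pr$mu_warped, pr$total_sd, w, model$train_ref),
    smse = smse(pr$mu_warped, w),
    ev = explained_variance(pr$mu_warped, w),
    rho = pearson_rho(pr$mu_warped, w),
    converged = model$converged)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC from
#' the two-way ANOVA decomposition of a complete subjects x iterations
#' matrix:
#' \deqn{\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E +
#'   \tfrac{k}{n}(MS_C - MS_E)}}
#' with n subjects (rows) and k iterations (columns). Used to quantify the
#' reliability of deviation scores across repeated subsampling draws.
#'
#' @param z_matrix numeric matrix, subjects x iterations, no missing values.
#' @return a single number.
#' @export
icc_2_1 <- function(z_matrix) {
  z_matrix <- as.matrix(z_matrix)
  n <- nrow(z_matrix); k <- ncol(z_matrix)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 iterations", call. = FALSE)
  if (anyNA(z_matrix))
    stop("incomplete matrix; ICC requires complete data", call. = FALSE)
  grand <- mean(z_matrix)
  row_m <- rowMeans(z_matrix)
  col_m <- colMeans(z_matrix)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- sum((z_matrix - outer(row_m, rep(1, k)) -
                   outer(rep(1, n), col_m) + grand)^2)
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k / n * (ms_c - ms_e))
}

#' Z-score error metrics against the full-sample reference
#'
#' `z_mse()` gives the per-subject mean over ROIs of the squared difference
#' between subsample and reference deviation scores; `iqr_keep()` implements
#' the conservative 3xIQR exclusion used before condition-level
#' summarization; `z_mbe()` gives per-ROI mean bias (negative = subsample
#' deviations more negative than reference, i.e. overestimated atrophy).
#'
#' @param z_sub,z_ref aligned subjects x ROIs deviation matrices (the
#'   reference comes from the full-training-set models).
#' @return `z_mse()`: named numeric vector (one value per subject).
#' @export
z_mse <- function(z_sub, z_ref) {
  check_aligned(z_sub, z_ref)
  rowMeans((z_sub - z_ref)^2)
}

#' @rdname z_mse
#' @param x numeric vector of per-subject errors pooled within a condition.
#' @param k IQR multiplier (default 3).
#' @return `iqr_keep()`: logical vector, `TRUE` for values inside
#'   `[Q1 - k IQR, Q3 + k IQR]`.
#' @export
iqr_keep <- function(x, k = 3) {
  q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2] - q[1]
  x >= q[1] - k * iqr & x <= q[2] + k * iqr
}

#' @rdname z_mse
#' @return `z_mbe()`: named numeric vector (one value per ROI).
#' @export
z_mbe <- function(z_sub, z_ref) {
  check_aligned(z_sub, z_ref)
  colMeans(z_sub - z_ref)
}

check_aligned <- function(z_sub, z_ref) {
  if (!all(dim(z_sub) == dim(z_ref)))
    stop("deviation matrices are not aligned", call. = FALSE)
  if (!is.null(rownames(z_sub)) && !is.null(rownames(z_ref)) &&
      !identical(rownames(z_sub), rownames(z_ref)))
    stop("deviation matrices have different subjects", call. = FALSE)
  if (!is.null(colnames(z_sub)) && !is.null(colnames(z_ref)) &&
      !identical(colnames(z_sub), colnames(z_ref)))
    stop("deviation matrices have different ROIs", call. = FALSE)
  invisible(TRUE)
}

#' Cubic age trend of per-subject error
#'
#' Least-squares cubic polynomial of per-subject MSE on age, used to locate
#' where in the age range deviation errors concentrate.
#'
#' @param mse per-subject error values.
#' @param ages ages in years, aligned with `mse`.
#' @return the fitted [stats::lm()] object (raw polynomial coefficients in
#'   `coef()`).
#' @export
age_error_curve <- function(mse, ages) {
  stopifnot(length(mse) == length(ages))
  if (length(unique(ages)) < 4)
    stop("need >= 4 distinct ages for a cubic fit", call. = FALSE)
  stats::lm(mse ~ stats::poly(ages, 3, raw = TRUE))
}
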