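#' Predict from a warped BLR normative model
#'
#' Returns, per subject, the warped-space conditional mean
#' \eqn{\mu_* = \phi(x)^\top\mu_w}, the epistemic variance
#' \eqn{\phi(x)^\top A^{-1}\phi(x)}, the aleatoric variance \eqn{1/\beta},
#' the full predictive SD (square root of their sum) and the point prediction
#' in original units, \eqn{\hat y = } unstandardize\eqn{(W^{-1}(\mu_*))}.
#' For adapted models (see [adapt_models()]) the site-specific mean offset
#' \eqn{\delta} is added to \eqn{\mu_*}; the variance is never touched.
#'
#' @param object a fitted [wblr()] model.
#' @param newdata cohort data frame; defaults to an error (normative models
#'   are always evaluated on explicit test subjects).
#' @param ... unused.
#' @return data frame with columns `mu_warped`, `epistemic_var`,
#'   `aleatoric_var`, `total_sd`, `yhat`.
#' @export
predict.wblr <- function(object, newdata, ...) {
  if (missing(newdata)) stop("`newdata` is required", call. = FALSE)
  if (is.null(object$chol_A))
    stop("model is not fitted (posterior unavailable)", call. = FALSE)
  newdata <- as.data.frame(newdata)
  if (!"site" %in% names(newdata)) newdata$site <- "site1"
  adapted <- !is.null(object$delta)
  Phi <- build_design(newdata, object$basis,
                      unseen_site = if (adapted) "zero" else "error")
  mu <- drop(Phi %*% object$weight_mean)
  if (adapted) {
    site <- as.character(newdata$site)
    miss <- setdiff(unique(site), names(object$delta))
    if (length(miss))
      stop("no adaptation offset for site(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    mu <- mu + unname(unlist(object$delta)[site])
  }
  # epistemic term phi' A^{-1} phi via the stored Cholesky factor
  V <- forwardsolve(t(object$chol_A), t(Phi))
  epi <- colSums(V^2)
  ale <- 1 / object$beta
  tsd <- sqrt(ale + epi)
  yhat <- object$y_center + object$y_scale *
    shash_inverse(mu, object$warp[["a"]], object$warp[["b"]])
  data.frame(mu_warped = mu, epistemic_var = epi, aleatoric_var = ale,
             total_sd = tsd, yhat = yhat)
}

#' Deviation (Z) scores
#'
#' \eqn{z = (W(\tilde y) - \mu_*) / \mathrm{sd}_{total}}, computed in warped
#' standardized space with the full (aleatoric + epistemic) predictive SD.
#' Atrophy (values below the normative curve) yields negative z. Missing ROI
#' values propagate as missing z.
#'
#' @param object fitted `wblr` model.
#' @param newdata cohort data frame containing the model's ROI column.
#' @param roi response column name; defaults to the fitted ROI.
#' @return numeric vector of z-scores, one per row of `newdata`.
#' @export
zscores <- function(object, newdata, roi = object$roi) {
  stopifnot(inherits(object, "wblr"))
  newdata <- as.data.frame(newdata)
  if (!roi %in% names(newdata))
    stop("ROI column not found in newdata: ", roi, call. = FALSE)
  pr <- predict(object, newdata)
  ystd <- (newdata[[roi]] - object$y_center) / object$y_scale
  w <- shash_warp(ystd, object$warp[["a"]], object$warp[["b"]])
  (w - pr$mu_warped) / pr$total_sd
}

#' Z-score matrix for a set of per-ROI models
#'
#' @param models named list of `wblr` fits (see [wblr_fit_rois()]).
#' @param newdata cohort data frame with the ROI columns.
#' @return numeric matrix, subjects x ROIs, rownames from `subject_id`.
#' @export
zscore_matrix <- function(models, newdata) {
  Z <- vapply(names(models), function(r) zscores(models[[r]], newdata, roi = r),
              numeric(nrow(newdata)))
  Z <- matrix(Z, nrow = nrow(newdata),
              dimnames = list(newdata$subject_id, names(models)))
  Z
}

#' Centile curves
#'
#' \eqn{centile_q(x) = } unstandardize\eqn{(W^{-1}(\mu_*(x) +
#' \mathrm{sd}_{total}(x)\,\Phi_N^{-1}(q)))}. Monotone in q by construction
#' (the warp is strictly increasing), so curves never cross.
#'
#' @param object fitted `wblr` model.
#' @param ages numeric grid of ages (years).
#' @param sex single sex label (`"F"` or `"M"`).
#' @param site single site label.
#' @param quantiles probabilities in (0, 1).
#' @return data frame with `age` and one column per quantile.
#' @export
centiles <- function(object, ages, sex = "F", site = NULL,
                     quantiles = c(0.05, 0.5, 0.95)) {
  stopifnot(inherits(object, "wblr"))
  if (any(quantiles <= 0 | quantiles >= 1))
    stop("quantiles must lie strictly in (0, 1)", call. = FALSE)
  site <- site %||% object$basis$site_levels[1L]
  nd <- data.frame(age = ages, sex = sex, site = site)
  pr <- predict(object, nd)
  out <- data.frame(age = ages)
  for (q in quantiles) {
    wq <- pr$mu_warped + pr$total_sd * stats::qnorm(q)
    out[[sprintf("q%g", 100 * q)]] <- object$y_center + object$y_scale *
      shash_inverse(wq, object$warp[["a"]], object$warp[["b"]])
  }
  out
}

#' @export
residuals.wblr <- function(object, newdata = NULL, type = c("z", "response"),
                           ...) {
  type <- match.arg(type)
  if (is.null(newdata))
    stop("supply `newdata`; training rows are not retained with covariates",
         call. = FALSE)
  if (type == "z") return(zscores(object, newdata))
  pr <- predict(object, newdata)
  newdata[[object$roi]] - pr$yhat
}

#' Simulate responses from the posterior predictive
#'
#' Draws warped-space responses \eqn{N(\mu_*, sd_{total}^2)} and maps them
#' back through \eqn{W^{-1}} and the standardizer, i.e. model-true data for
#' the fitted model.
#'
#' @param object fitted `wblr` model.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param newdata covariate data frame.
#' @param ... unused.
#' @return data frame with `nsim` columns.
#' @export
simulate.wblr <- function(object, nsim = 1, seed = 1L, newdata, ...) {
  pr <- predict(object, newdata)
  n <- nrow(pr)
  with_seed(seed, {
    sims <- replicate(nsim, {
      w <- stats::rnorm(n, pr$mu_warped, pr$total_sd)
      object$y_center + object$y_scale *
        shash_inverse(w, object$warp[["a"]], object$warp[["b"]])
    })
    as.data.frame(matrix(sims, nrow = n,
                         dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
  })
}

#' @export
coef.wblr <- function(object, ...) object$weight_mean

#' @export
print.wblr <- function(x, ...) {
  cat("Warped BLR normative model:", x$roi, "\n")
  cat(sprintf("  n = %d training subjects, %d design columns\n", x$n, x$d))
  cat(sprintf("  warp (a, b) = (%.3f, %.3f)   alpha = %.3g   beta = %.3g\n",
              x$warp[["a"]], x$warp[["b"]], x$alpha, x$beta))
  cat(sprintf("  NLL = %.3f   converged: %s\n", x$nll, x$converged))
  invisible(x)
}

#' @export
summary.wblr <- function(object, ...) {
  structure(list(model = object), class = "summary.wblr")
}

#' @export
print.summary.wblr <- function(x, ...) {
  m <- x$model
  print(m)
  cat(sprintf("  optimizer: Powell, %d iterations (~%d evaluations)\n",
              m$optim$iterations, m$optim$fevals))
  cat(sprintf("  aleatoric var 1/beta = %.4f\n", 1 / m$beta))
  cat(sprintf("  warped training reference: mean %.4f, var %.4f\n",
              m$train_ref$mean, m$train_ref$var))
  invisible(x)
}

#' Centile plot for a fitted normative model
#'
#' @param x fitted `wblr` model.
#' @param data optional cohort data frame scattered behind the curves.
#' @param sex,site covariate cell for the curves.
#' @param quantiles centiles to draw.
#' @param ... passed to [graphics::plot()].
#' @export
plot.wblr <- function(x, data = NULL, sex = "F", site = NULL,
                      quantiles = c(0.05, 0.5, 0.95), ...) {
  rng <- x$basis$age_center + x$basis$age_scale * x$basis$span
  ages <- seq(rng[1], rng[2], length.out = 100)
  cc <- centiles(x, ages, sex = sex, site = site, quantiles = quantiles)
  ylim <- range(unlist(cc[-1]), if (!is.null(data)) data[[x$roi]])
  graphics::plot(NA, xlim = rng, ylim = ylim, xlab = "age (years)",
                 ylab = x$roi, ...)
  if (!is.null(data))
    graphics::points(data$age, data[[x$roi]], pch = 16, cex = 0.4,
                     col = "grey60")
  for (j in seq_along(quantiles))
    graphics::lines(cc$age, cc[[j + 1L]], lwd = if (quantiles[j] == 0.5) 2 else 1)
  invisible(cc)
}
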