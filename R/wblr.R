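#' Negative log marginal likelihood of the warped Bayesian linear model
#'
#' For hyperparameters \eqn{\theta = (\log\alpha, \log\beta, a, \log b)} the
#' responses are warped, \eqn{\tilde y = W(y; a, b)}, and the negative log
#' evidence of the Gaussian linear model
#' \deqn{-\left[\tfrac{D}{2}\ln\alpha + \tfrac{N}{2}\ln\beta - E(\mu_w)
#'   - \tfrac12\ln|A| - \tfrac{N}{2}\ln 2\pi\right]}
#' with \eqn{A = \alpha I + \beta\Phi^\top\Phi},
#' \eqn{\mu_w = \beta A^{-1}\Phi^\top\tilde y} and
#' \eqn{E = \tfrac\beta2\|\tilde y - \Phi\mu_w\|^2 + \tfrac\alpha2
#' \mu_w^\top\mu_w} is returned, minus the warp Jacobian term
#' \eqn{\sum_i \ln W'(y_i; a, b)}.
#'
#' @param theta numeric length-4 vector `(log alpha, log beta, a, log b)`.
#' @param design design matrix \eqn{\Phi} (see [build_design()]).
#' @param y standardized responses.
#' @return a single number; attributes `mu_w` and `chol_A` carry the posterior
#'   at `theta` so the fitter does not recompute it.
#' @export
wblr_nll <- function(theta, design, y) {
  stopifnot(length(theta) == 4L, nrow(design) == length(y))
  alpha <- exp(theta[1]); beta <- exp(theta[2])
  a <- theta[3]; b <- exp(theta[4])
  n <- length(y); d <- ncol(design)
  w <- shash_warp(y, a, b)
  A <- alpha * diag(d) + beta * crossprod(design)
  R <- tryCatch(chol(A), error = function(e)
    stop("precision matrix numerically singular; use more data or a stronger prior",
         call. = FALSE))
  mu <- beta * backsolve(R, forwardsolve(t(R), crossprod(design, w)))
  resid <- w - design %*% mu
  E <- beta / 2 * sum(resid^2) + alpha / 2 * sum(mu^2)
  logdetA <- 2 * sum(log(diag(R)))
  evidence <- d / 2 * log(alpha) + n / 2 * log(beta) - E -
    logdetA / 2 - n / 2 * log(2 * pi)
  jac <- sum(log(shash_derivative(y, a, b)))
  out <- -evidence - jac
  attr(out, "mu_w") <- drop(mu)
  attr(out, "chol_A") <- R
  out
}

#' Fit a warped Bayesian linear regression normative model
#'
#' Fits one region of interest with an intercept + cubic B-spline(age) + sex +
#' site-dummy design, a sinh-arcsinh warped Gaussian likelihood, and type-II
#' maximum likelihood over \eqn{(\alpha, \beta, a, b)} using Powell's
#' conjugate direction method from the Gaussian-null start
#' \eqn{(\log\alpha, \log\beta, a, \log b) = (0,0,0,0)}. The response and age
#' are z-standardized on the training set; the constants are stored for
#' inversion. Non-convergence within the iteration budget does not raise an
#' error: the model is returned with `converged = FALSE` (very small training
#' sets, e.g. n = 5, routinely produce unstable fits).
#'
#' @param formula e.g. `Left_Hippocampus ~ age + sex + site`; the left-hand
#'   side names the ROI column, the right-hand side selects which of the
#'   `age`, `sex`, `site` covariates enter the design (age is required).
#' @param data training cohort data frame (healthy controls).
#' @param basis a [basis_spec()].
#' @param warp `TRUE` to estimate the SHASH warp; `FALSE` freezes the
#'   identity warp `(a, b) = (0, 1)` (plain Bayesian linear regression).
#' @param start start point for `(log alpha, log beta, a, log b)`.
#' @param control list with `reltol` (default `1e-6`) and `maxit`
#'   (default `500`) for the Powell loop.
#' @return an object of class `wblr`.
#' @seealso [predict.wblr()], [zscores()], [centiles()], [simulate.wblr()]
#' @examples
#' coh <- generate_cohort(cohort_spec(n_hc = 200, n_ad = 0, n_rois = 1, seed = 1))
#' m <- wblr(roi_001 ~ age + sex + site, data = coh)
#' summary(m)
#' @export
wblr <- function(formula, data, basis = basis_spec(), warp = TRUE,
                 start = c(0, 0, 0, 0), control = list()) {
  cl <- match.call()
  reltol <- control$reltol %||% 1e-6
  maxit <- control$maxit %||% 500L
  vars <- all.vars(formula)
  roi <- vars[1L]
  rhs <- vars[-1L]
  if (!"age" %in% rhs)
    stop("the model requires `age` on the right-hand side", call. = FALSE)
  if (!roi %in% names(data))
    stop("response column not found: ", roi, call. = FALSE)
  data <- as.data.frame(data)
  if (!"site" %in% rhs || !"site" %in% names(data)) data$site <- "site1"
  if (!"sex" %in% rhs) basis$use_sex <- FALSE
  basis <- basis_prepare(basis, data)
  y_raw <- data[[roi]]
  if (anyNA(y_raw)) stop("missing response values in training data", call. = FALSE)
  y_center <- mean(y_raw)
  y_scale <- stats::sd(y_raw)
  if (!is.finite(y_scale) || y_scale <= 0)
    stop("constant training response; cannot standardize", call. = FALSE)
  y <- (y_raw - y_center) / y_scale
  Phi <- build_design(data, basis)
  n <- nrow(Phi); d <- ncol(Phi)

  safe_nll <- function(th) {
    v <- tryCatch(as.numeric(wblr_nll(th, Phi, y)), error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  if (warp) {
    obj <- safe_nll
    theta0 <- start
  } else {
    obj <- function(th2) safe_nll(c(th2[1], th2[2], 0, 0))
    theta0 <- start[1:2]
  }
  opt <- powell_minimize(obj, theta0, reltol = reltol, maxit = maxit)
  theta <- if (warp) opt$par else c(opt$par, 0, 0)
  nll_start <- safe_nll(if (warp) start else c(start[1:2], 0, 0))

  fit_ok <- is.finite(opt$value) && opt$value < 1e10
  post <- tryCatch(wblr_nll(theta, Phi, y), error = function(e) NULL)
  if (is.null(post)) fit_ok <- FALSE
  a <- theta[3]; b <- exp(theta[4])
  w_train <- shash_warp(y, a, b)

  structure(list(
    call = cl, formula = formula, roi = roi,
    basis = basis,
    theta = stats::setNames(theta, c("log_alpha", "log_beta", "a", "log_b")),
    alpha = exp(theta[1]), beta = exp(theta[2]),
    warp = c(a = a, b = b),
    weight_mean = if (fit_ok) stats::setNames(attr(post, "mu_w"), colnames(Phi))
                  else stats::setNames(rep(NA_real_, d), colnames(Phi)),
    chol_A = if (fit_ok) attr(post, "chol_A") else NULL,
    y_center = y_center, y_scale = y_scale,
    train_ref = list(mean = mean(w_train), var = stats::var(w_train)),
    nll = as.numeric(opt$value), nll_start = nll_start,
    converged = opt$converged && fit_ok,
    n = n, d = d,
    optim = list(iterations = opt$iterations, fevals = opt$fevals),
    train_y = y_raw),
    class = "wblr")
}

#' Fit one normative model per ROI
#'
#' Convenience wrapper running [wblr()] independently for each named ROI
#' column (the benchmark fits every region independently; no cross-ROI
#' sharing).
#'
#' @param data training cohort.
#' @param rois character vector of ROI column names; defaults to every column
#'   after the demographic block.
#' @param ... passed to [wblr()].
#' @return named list of `wblr` objects.
#' @export
wblr_fit_rois <- function(data, rois = roi_columns(data), ...) {
  out <- lapply(rois, function(r) {
    f <- stats::as.formula(paste(r, "~ age + sex + site"))
    m <- wblr(f, data, ...)
    m$call <- NULL
    m
  })
  stats::setNames(out, rois)
}

#' @rdname wblr_fit_rois
#' @param data cohort data frame.
#' @export
roi_columns <- function(data) {
  setdiff(names(data), c("subject_id", "age", "sex", "site", "diagnosis"))
}
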