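# Independent oracle: the marginal likelihood of the Bayesian linear model
# written as a multivariate Gaussian over the responses,
# y ~ N(0, I/beta + Phi Phi' / alpha), plus the warp Jacobian. This shares
# no linear algebra with the A = alpha I + beta Phi'Phi route in wblr_nll().
nll_oracle <- function(theta, Phi, y) {
  alpha <- exp(theta[1]); beta <- exp(theta[2])
  a <- theta[3]; b <- exp(theta[4])
  w <- shash_warp(y, a, b)
  C <- diag(length(y)) / beta + Phi %*% t(Phi) / alpha
  0.5 * (length(y) * log(2 * pi) + determinant(C)$modulus[1] +
           drop(t(w) %*% solve(C, w))) -
    sum(log(shash_derivative(y, a, b)))
}

test_that("NLL matches hand linear algebra on the two-point example", {
  Phi <- matrix(1, 2, 1)
  y <- c(0, 2)
  v <- wblr_nll(c(0, 0, 0, 0), Phi, y)     # alpha = beta = 1, identity warp
  expect_equal(drop(attr(v, "mu_w")), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(attr(v, "chol_A")[1, 1]^2), 3, tolerance = 1e-12)
  # posterior predictive at phi = 1: mean 2/3, variance 1/beta + 1/A = 4/3
  expect_equal(1 + 1 / 3, 4 / 3)
  expect_equal(as.numeric(v), nll_oracle(c(0, 0, 0, 0), Phi, y),
               tolerance = 1e-10)
})

test_that("NLL agrees with the direct-summation oracle at random points", {
  set.seed(42)
  Phi <- cbind(1, rnorm(10), runif(10))
  y <- rnorm(10)
  for (i in 1:6) {
    theta <- c(runif(1, -1, 1), runif(1, -1, 1), runif(1, -0.8, 0.8),
               runif(1, -0.5, 0.5))
    expect_equal(as.numeric(wblr_nll(theta, Phi, y)),
                 nll_oracle(theta, Phi, y), tolerance = 1e-8)
  }
})

test_that("frozen identity warp reproduces textbook Bayesian linear regression", {
  coh <- gaussian_cohort()
  m <- wblr(roi_001 ~ age + sex + site, coh, warp = FALSE)
  expect_equal(unname(m$warp), c(0, 1))
  # closed-form posterior at the fitted hyperparameters
  Phi <- build_design(coh, m$basis)
  y <- (coh$roi_001 - m$y_center) / m$y_scale
  A <- m$alpha * diag(ncol(Phi)) + m$beta * crossprod(Phi)
  mu <- m$beta * solve(A, crossprod(Phi, y))
  expect_equal(unname(m$weight_mean), unname(drop(mu)), tolerance = 1e-8)
  pr <- predict(m, coh[1:5, ])
  phi <- Phi[1:5, , drop = FALSE]
  expect_equal(pr$mu_warped, drop(phi %*% mu), tolerance = 1e-8)
  expect_equal(pr$epistemic_var, diag(phi %*% solve(A, t(phi))),
               tolerance = 1e-8)
  # identity warp: point prediction is the unstandardized warped mean
  expect_equal(pr$yhat, m$y_center + m$y_scale * pr$mu_warped,
               tolerance = 1e-10)
})

test_that("optimizer never ends above its start point and flags convergence", {
  m <- small_model()
  expect_lte(m$nll, m$nll_start)
  expect_true(is.logical(m$converged))
})

test_that("five training subjects fit without crashing", {
  sc <- small_cohort()
  tiny <- sc$train[1:5, ]
  expect_no_error(m <- wblr(roi_001 ~ age + sex + site, tiny,
                            control = list(maxit = 50)))
  expect_s3_class(m, "wblr")
})

test_that("z-score is zero on the predicted mean and negative below it", {
  m <- small_model()
  sc <- small_cohort()
  nd <- sc$test[1:4, ]
  pr <- predict(m, nd)
  # place observations exactly on the warped conditional mean
  nd[[m$roi]] <- m$y_center + m$y_scale *
    shash_inverse(pr$mu_warped, m$warp[["a"]], m$warp[["b"]])
  expect_equal(zscores(m, nd), rep(0, 4), tolerance = 1e-10)
  nd[[m$roi]] <- nd[[m$roi]] - 10 * m$y_scale   # far below the curve
  expect_true(all(zscores(m, nd) < -1.96))
})

test_that("HC test z-scores are calibrated to mean 0, variance 1 on model-true data", {
  # one n = 1000 test draw has sd(var) ~ 0.063, so the calibration bound is
  # checked on the median over five independent replicates plus pooled moments
  stats <- vapply(1:5, function(s) {
    coh <- generate_cohort(cohort_spec(n_hc = 5000, n_ad = 0, n_rois = 1,
                                       seed = 200 + s))
    sp <- stratified_split(coh, 0.8, seed = 200 + s)
    m <- wblr(roi_001 ~ age + sex + site, sp$train)
    z <- zscores(m, sp$test)
    c(mean = mean(z), var = var(z), n = length(z))
  }, numeric(3))
  expect_lt(abs(sum(stats["mean", ] * stats["n", ]) / sum(stats["n", ])), 0.05)
  expect_lt(median(abs(stats["var", ] - 1)), 0.1)
})

test_that("epistemic uncertainty shrinks on nested training sets", {
  sc <- small_cohort()
  probe <- sc$test[1:10, ]
  sizes <- c(50, 150, 400)
  epi <- vapply(sizes, function(n) {
    m <- wblr(roi_001 ~ age + sex + site, sc$train[seq_len(n), ])
    mean(predict(m, probe)$epistemic_var)
  }, numeric(1))
  expect_true(all(diff(epi) < 0))
})

test_that("centiles are non-crossing, ordered, and Gaussian-exact for the identity warp", {
  coh <- gaussian_cohort()
  m <- wblr(roi_001 ~ age + sex + site, coh, warp = FALSE)
  ages <- seq(46, 81, length.out = 30)
  cc <- centiles(m, ages, sex = "F", quantiles = c(0.05, 0.5, 0.95))
  expect_true(all(cc$q5 < cc$q50 & cc$q50 < cc$q95))
  # a = 0: the median curve is the point prediction
  nd <- data.frame(age = ages, sex = "F", site = m$basis$site_levels[1])
  pr <- predict(m, nd)
  expect_equal(cc$q50, pr$yhat, tolerance = 1e-10)
  # identity warp: q95 = mu + 1.6449 sd, analytically
  expect_equal(cc$q95,
               m$y_center + m$y_scale *
                 (pr$mu_warped + qnorm(0.95) * pr$total_sd),
               tolerance = 1e-10)
  expect_error(centiles(m, ages, quantiles = c(0, 0.5)), "quantiles")
})

test_that("simulated responses reproduce the model's own z-score distribution", {
  m <- small_model()
  sc <- small_cohort()
  nd <- sc$test
  sim <- simulate(m, nsim = 1, seed = 9, newdata = nd)
  nd[[m$roi]] <- sim[[1]]
  z <- zscores(m, nd)
  expect_gt(stats::ks.test(z, "pnorm")$p.value, 0.01)
})

test_that("missing ROI values propagate as missing z-scores", {
  m <- small_model()
  sc <- small_cohort()
  nd <- sc$test[1:5, ]
  nd[[m$roi]][2] <- NA
  z <- zscores(m, nd)
  expect_true(is.na(z[2]) && !anyNA(z[-2]))
})
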