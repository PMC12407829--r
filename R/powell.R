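# Powell's conjugate direction method (derivative-free), with Brent line
# minimization along each direction and the standard direction-replacement
# rule. Used to minimize the warped-BLR negative log marginal likelihood;
# no installed optimizer exposes Powell's method, so it is implemented here.
powell_minimize <- function(fn, par, reltol = 1e-6, maxit = 500L,
                            line_interval = c(-3, 3), line_tol = 1e-5) {
  n <- length(par)
  dirs <- diag(n)
  f <- fn(par)
  fevals <- 1L
  converged <- FALSE
  iters <- 0L
  line_min <- function(p, d) {
    opt <- stats::optimize(function(t) fn(p + t * d),
                           interval = line_interval, tol = line_tol)
    opt
  }
  for (it in seq_len(maxit)) {
    iters <- it
    f0 <- f
    p0 <- par
    biggest_drop <- 0
    biggest_i <- 0L
    for (i in seq_len(n)) {
      d <- dirs[, i]
      opt <- line_min(par, d)
      fevals <- fevals + 20L  # optimize() evaluation count is not exposed
      if (opt$objective < f) {
        if (f - opt$objective > biggest_drop) {
          biggest_drop <- f - opt$objective
          biggest_i <- i
        }
        par <- par + opt$minimum * d
        f <- opt$objective
      }
    }
    if (2 * (f0 - f) <= reltol * (abs(f0) + abs(f)) + 1e-12) {
      converged <- TRUE
      break
    }
    # extrapolated point test: replace the direction of largest decrease
    # with the overall displacement if that is profitable (Powell 1964)
    ext <- 2 * par - p0
    f_ext <- fn(ext)
    fevals <- fevals + 1L
    if (f_ext < f0) {
      t1 <- 2 * (f0 - 2 * f + f_ext) * (f0 - f - biggest_drop)^2
      t2 <- biggest_drop * (f0 - f_ext)^2
      if (t1 < t2 && biggest_i > 0L) {
        dnew <- par - p0
        nd <- sqrt(sum(dnew^2))
        if (nd > 0) {
          dirs[, biggest_i] <- dirs[, n]
          dirs[, n] <- dnew / nd
          opt <- line_min(par, dirs[, n])
          fevals <- fevals + 20L
          if (opt$objective < f) {
            par <- par + opt$minimum * dirs[, n]
            f <- opt$objective
          }
        }
      }
    }
  }
  list(par = par, value = f, converged = converged,
       iterations = iters, fevals = fevals)
}
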