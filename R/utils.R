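# Internal helpers shared across the package.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All user-facing randomness goes through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

# Deterministic per-condition seed: positional encoding of (root_seed,
# strategy index, n, iteration). Injective within a run (strategy < 100,
# n < 10000, iteration < 100) and kept below 2^31.
derive_seed <- function(root_seed, strategy_index, n, iteration) {
  root <- as.double(root_seed) %% 2017
  s <- root * 1e8 + as.double(strategy_index) * 1e6 +
    as.double(n) * 1e2 + as.double(iteration)
  as.integer(s %% .Machine$integer.max)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
    stop(sprintf("`%s` must be a single number in (0, 1)", name), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
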