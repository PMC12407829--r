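#' Subsampling condition
#'
#' One training-subset condition of the benchmark: a strategy, a target size,
#' an iteration index and a seed. Age manipulation uses 10 bins: quantile
#' bins (equal occupancy) for representative sampling, equal-width bins
#' weighted by a Beta density at the bin midpoints for the skewed strategies
#' — Beta(2, 5) oversamples the young (left-skewed), Beta(5, 2) the old
#' (right-skewed). The sex-imbalanced strategy fixes the female:male ratio
#' and draws ages representatively within each sex.
#'
#' @param strategy one of `"representative"`, `"left_skewed"`,
#'   `"right_skewed"`, `"sex_imbalanced"`.
#' @param n target sample size.
#' @param n_bins number of age bins (10).
#' @param sex_ratio length-2 positive vector `(n_f, n_m)`; only used by
#'   `sex_imbalanced` (e.g. `c(1, 4)`, `c(10, 1)`).
#' @param iteration iteration index (bookkeeping only).
#' @param seed integer seed.
#' @return object of class `sampling_spec`.
#' @export
sampling_spec <- function(strategy = c("representative", "left_skewed",
                                       "right_skewed", "sex_imbalanced"),
                          n, n_bins = 10L, sex_ratio = c(1, 1),
                          iteration = 1L, seed = 1L) {
  strategy <- match.arg(strategy)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  if (length(sex_ratio) != 2 || any(sex_ratio <= 0))
    stop("sex_ratio must be two positive numbers", call. = FALSE)
  beta_params <- switch(strategy, left_skewed = c(2, 5),
                        right_skewed = c(5, 2), NULL)
  structure(list(strategy = strategy, n = as.integer(n),
                 n_bins = as.integer(n_bins), beta_params = beta_params,
                 sex_ratio = sex_ratio, iteration = as.integer(iteration),
                 seed = as.integer(seed)),
            class = "sampling_spec")
}

#' Quantile age bins
#'
#' Partitions subjects into `n_bins` bins with equal occupancy (counts differ
#' by at most one; the first bins take the remainder), ordered by age, ties
#' broken by stable input order. With all ages identical the assignment is
#' still deterministic (input order).
#'
#' @param ages numeric vector.
#' @param n_bins number of bins.
#' @return integer vector of bin indices (1-based), same order as `ages`.
#' @export
quantile_bins <- function(ages, n_bins = 10L) {
  n <- length(ages)
  if (n < n_bins) stop("fewer subjects than bins", call. = FALSE)
  ord <- order(ages)                      # stable for ties
  base <- n %/% n_bins
  sizes <- rep(base, n_bins)
  rem <- n - base * n_bins
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  bins <- integer(n)
  bins[ord] <- rep(seq_len(n_bins), times = sizes)
  bins
}

# Allocate per-bin draw targets and select subjects without replacement,
# balancing sexes globally to |#F - #M| <= 1 where availability permits
# (per-bin balancing first, residual corrected by redistribution).
# Runs inside a seeded context.
balanced_bin_draw <- function(pool, bins, targets, balance_sex = TRUE) {
  n_bins <- length(targets)
  sel <- integer(0)
  if (!balance_sex) {
    for (b in seq_len(n_bins)) {
      idx <- which(bins == b)
      k <- min(targets[b], length(idx))
      if (k > 0) sel <- c(sel, idx[sample.int(length(idx), k)])
    }
    return(sel)
  }
  n <- sum(targets)
  nF <- n %/% 2L
  if (n %% 2L == 1L && stats::runif(1) < 0.5) nF <- nF + 1L
  nM <- n - nF
  # per-bin sex targets: halves, with odd bins randomly rounded toward F
  # until the global female target is met
  fF <- targets %/% 2L
  odd <- which(targets %% 2L == 1L)
  need <- nF - sum(fF)
  if (need > 0 && length(odd)) {
    up <- odd[sample.int(length(odd), min(need, length(odd)))]
    fF[up] <- fF[up] + 1L
  }
  fM <- targets - fF
  sexes <- attr(bins, "sex")
  short <- 0L
  for (b in seq_len(n_bins)) {
    iF <- which(bins == b & sexes == "F")
    iM <- which(bins == b & sexes == "M")
    kF <- min(fF[b], length(iF))
    kM <- min(fM[b], length(iM))
    deficit <- targets[b] - kF - kM
    # fill a within-bin deficit from whichever sex still has members
    if (deficit > 0) {
      spareF <- length(iF) - kF; spareM <- length(iM) - kM
      addF <- min(deficit, spareF); kF <- kF + addF; deficit <- deficit - addF
      addM <- min(deficit, spareM); kM <- kM + addM; deficit <- deficit - addM
      short <- short + deficit
    }
    if (kF > 0) sel <- c(sel, iF[sample.int(length(iF), kF)])
    if (kM > 0) sel <- c(sel, iM[sample.int(length(iM), kM)])
  }
  # redistribute any residual shortfall across bins, preferring the
  # underrepresented sex
  while (length(sel) < n) {
    remaining <- setdiff(seq_along(bins), sel)
    if (!length(remaining)) break
    cnt <- table(factor(sexes[sel], levels = c("F", "M")))
    prefer <- if (cnt[["F"]] <= cnt[["M"]]) "F" else "M"
    cand <- remaining[sexes[remaining] == prefer]
    if (!length(cand)) cand <- remaining
    sel <- c(sel, cand[sample.int(length(cand), 1L)])
  }
  cnt <- table(factor(sexes[sel], levels = c("F", "M")))
  if (abs(cnt[["F"]] - cnt[["M"]]) > 1L)
    message("sex balance not attainable from pool: ",
            cnt[["F"]], " F vs ", cnt[["M"]], " M")
  sel
}

#' Draw a training subsample
#'
#' Dispatches on the strategy of a [sampling_spec()]. All draws are without
#' replacement and deterministic under the spec's seed.
#'
#' @param pool cohort data frame (the training HC pool).
#' @param spec a [sampling_spec()].
#' @return subset of `pool` with `spec$n` rows.
#' @export
draw_sample <- function(pool, spec) {
  stopifnot(inherits(spec, "sampling_spec"))
  if (spec$n > nrow(pool))
    stop("requested sample size exceeds pool size", call. = FALSE)
  switch(spec$strategy,
         representative = representative_sample(pool, spec),
         left_skewed = skewed_sample(pool, spec),
         right_skewed = skewed_sample(pool, spec),
         sex_imbalanced = sex_imbalanced_sample(pool, spec))
}

#' @rdname draw_sample
#' @export
representative_sample <- function(pool, spec) {
  stopifnot(spec$strategy == "representative" || spec$strategy == "sex_imbalanced")
  if (spec$n > nrow(pool)) stop("n exceeds pool size", call. = FALSE)
  bins <- quantile_bins(pool$age, spec$n_bins)
  attr(bins, "sex") <- as.character(pool$sex)
  with_seed(spec$seed, {
    targets <- bin_targets(spec$n, spec$n_bins)
    sel <- balanced_bin_draw(pool, bins, targets, balance_sex = TRUE)
    take_rows(pool, sel)
  })
}

# per-bin totals: as equal as arithmetic allows, remainder spread over
# randomly chosen distinct bins (call inside a seeded context)
bin_targets <- function(n, n_bins) {
  base <- n %/% n_bins
  targets <- rep(base, n_bins)
  rem <- n - base * n_bins
  if (rem > 0) {
    up <- sample.int(n_bins, rem)
    targets[up] <- targets[up] + 1L
  }
  targets
}

#' @rdname draw_sample
#' @export
skewed_sample <- function(pool, spec) {
  stopifnot(spec$strategy %in% c("left_skewed", "right_skewed"))
  if (spec$n > nrow(pool)) stop("n exceeds pool size", call. = FALSE)
  nb <- spec$n_bins
  rng <- range(pool$age)
  # equal-width bins over the pool age range; right edge closes the last bin
  edges <- seq(rng[1], rng[2], length.out = nb + 1L)
  bins <- findInterval(pool$age, edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
  attr(bins, "sex") <- as.character(pool$sex)
  mid <- (seq_len(nb) - 0.5) / nb
  w <- stats::dbeta(mid, spec$beta_params[1], spec$beta_params[2])
  capacity <- tabulate(bins, nbins = nb)
  with_seed(spec$seed, {
    targets <- allocate_multinomial(spec$n, w, capacity)
    sel <- balanced_bin_draw(pool, bins, targets, balance_sex = TRUE)
    take_rows(pool, sel)
  })
}

# multinomial allocation with bin-exhaustion handling: excess over a bin's
# capacity is re-allocated over the remaining bins with renormalized weights
allocate_multinomial <- function(n, w, capacity) {
  nb <- length(w)
  targets <- rep(0L, nb)
  remaining <- n
  open <- capacity > 0
  while (remaining > 0 && any(open)) {
    ww <- ifelse(open, w, 0)
    draw <- as.integer(stats::rmultinom(1, remaining, ww / sum(ww)))
    targets <- targets + pmin(draw, capacity - targets)
    remaining <- n - sum(targets)
    open <- capacity - targets > 0
  }
  targets
}

#' @rdname draw_sample
#' @export
sex_imbalanced_sample <- function(pool, spec) {
  stopifnot(spec$strategy == "sex_imbalanced")
  if (spec$n > nrow(pool)) stop("n exceeds pool size", call. = FALSE)
  nf <- round(spec$n * spec$sex_ratio[1] / sum(spec$sex_ratio))
  nm <- spec$n - nf
  counts <- c(F = nf, M = nm)
  avail <- table(factor(as.character(pool$sex), levels = c("F", "M")))
  for (s in c("F", "M"))
    if (counts[[s]] > avail[[s]])
      stop(sprintf("insufficient %s subjects: need %d, have %d",
                   s, counts[[s]], avail[[s]]), call. = FALSE)
  with_seed(spec$seed, {
    sel <- integer(0)
    for (s in c("F", "M")) {
      k <- counts[[s]]
      if (k == 0L) next
      idx <- which(pool$sex == s)
      sub <- pool[idx, , drop = FALSE]
      bins <- quantile_bins(sub$age, min(spec$n_bins, nrow(sub)))
      targets <- bin_targets(k, max(bins))
      picked <- balanced_bin_draw(sub, bins, targets, balance_sex = FALSE)
      sel <- c(sel, idx[picked])
    }
    take_rows(pool, sel)
  })
}

take_rows <- function(pool, sel) {
  out <- pool[sort(sel), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "spec") <- attr(pool, "spec")
  out
}

#' Benchmark size grid
#'
#' The benchmark's sample-size ladder: increments of 5 from 5 to 200, then
#' increments of 50 up to 600, plus the full training pool (single
#' iteration).
#'
#' @param sizes strictly increasing sizes.
#' @param iterations_per_size random draws per size (default 10).
#' @param include_full whether to append the full-pool condition.
#' @return object of class `size_grid`.
#' @export
size_grid <- function(sizes = c(seq(5L, 200L, 5L), seq(250L, 600L, 50L)),
                      iterations_per_size = 10L, include_full = TRUE) {
  if (any(diff(sizes) <= 0)) stop("sizes must be strictly increasing", call. = FALSE)
  structure(list(sizes = as.integer(sizes),
                 iterations_per_size = as.integer(iterations_per_size),
                 include_full = isTRUE(include_full)),
            class = "size_grid")
}

#' Enumerate all benchmark conditions
#'
#' Cartesian product of sizes x strategies x iterations with deterministic
#' derived seeds; the full-size condition has a single iteration. `strategies`
#' may be strategy names or `sampling_spec`-like lists carrying a `sex_ratio`
#' (a name like `"sex_imbalanced_1_4"` encodes the ratio).
#'
#' @param grid a [size_grid()].
#' @param strategies character vector of strategy labels.
#' @param root_seed integer root seed for seed derivation.
#' @return list of [sampling_spec()] objects; `attr(, "manifest")` holds a
#'   data frame (strategy, n, iteration, seed).
#' @export
enumerate_conditions <- function(grid, strategies = "representative",
                                 root_seed = 1L) {
  stopifnot(inherits(grid, "size_grid"))
  specs <- list()
  rows <- list()
  for (si in seq_along(strategies)) {
    lab <- strategies[si]
    parsed <- parse_strategy(lab)
    for (n in grid$sizes) {
      for (it in seq_len(grid$iterations_per_size)) {
        sd <- derive_seed(root_seed, si, n, it)
        specs[[length(specs) + 1L]] <- sampling_spec(
          parsed$strategy, n = n, sex_ratio = parsed$sex_ratio,
          iteration = it, seed = sd)
        rows[[length(rows) + 1L]] <-
          data.frame(strategy = lab, n = n, iteration = it, seed = sd)
      }
    }
  }
  out <- specs
  attr(out, "manifest") <- do.call(rbind, rows)
  out
}

parse_strategy <- function(label) {
  if (grepl("^sex_imbalanced", label)) {
    m <- regmatches(label, regexec("sex_imbalanced_?(\\d+)?_?(\\d+)?", label))[[1]]
    ratio <- if (!is.na(m[2]) && nzchar(m[2]) && nzchar(m[3]))
      as.numeric(c(m[2], m[3])) else c(1, 1)
    list(strategy = "sex_imbalanced", sex_ratio = ratio)
  } else {
    list(strategy = label, sex_ratio = c(1, 1))
  }
}
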