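#' Pre-train normative models on a large reference cohort
#'
#' Fits per-ROI [wblr()] models on 80% of an HC-only reference cohort
#' (stratified split) and evaluates them on the internal 20% holdout. These
#' models are the starting point for mean-level transfer adaptation to a
#' target cohort.
#'
#' @param reference HC-only cohort data frame.
#' @param rois ROI columns to fit (default: all measurement columns).
#' @param train_fraction internal split fraction (default 0.8).
#' @param seed integer seed for the split.
#' @param ... passed to [wblr()].
#' @return list with `models` (named list of `wblr`), `holdout_metrics`
#'   (per-ROI fit metrics on the internal holdout) and `split`.
#' @export
pretrain <- function(reference, rois = roi_columns(reference),
                     train_fraction = 0.8, seed = 1L, ...) {
  if (!all(reference$diagnosis == "HC"))
    stop("reference cohort must be HC-only", call. = FALSE)
  sp <- stratified_split(reference, train_fraction, seed = seed)
  models <- wblr_fit_rois(sp$train, rois, ...)
  hm <- do.call(rbind, lapply(rois, function(r)
    cbind(roi = r, fit_metrics(models[[r]], sp$test))))
  rownames(hm) <- NULL
  list(models = models, holdout_metrics = hm, split = sp)
}

#' Adapt pre-trained models to a target cohort (mean-level recalibration)
#'
#' For each ROI and target site, estimates the warped-space mean offset
#' \eqn{\delta = \mathrm{mean}(W(\tilde y) - \mu_*)} over the HC adaptation
#' subjects and stores it on the model; predictions become
#' \eqn{\mu_*' = \mu_* + \delta} while the predictive variance, warp, and
#' weights are untouched — so explained variance, correlation and the
#' within-cell ranking of deviation scores are exactly invariant. Target
#' site labels unseen by the reference basis have their site-dummy block
#' zeroed; the site effect is absorbed entirely into \eqn{\delta}. The
#' reference standardizer is reused (offsets must live on a common scale).
#'
#' @param models named list of pre-trained `wblr` models (see [pretrain()]).
#' @param adaptation HC adaptation subjects from the target cohort.
#' @return the models with `$delta` (named per target site) and `$n_adapt`
#'   set; `attr(, "offsets")` is a long data frame (roi, target_site, delta,
#'   n_adapt).
#' @export
adapt_models <- function(models, adaptation) {
  if (nrow(adaptation) == 0)
    stop("empty adaptation set", call. = FALSE)
  if ("diagnosis" %in% names(adaptation) &&
      !all(adaptation$diagnosis == "HC"))
    stop("adaptation subjects must be healthy controls", call. = FALSE)
  sites <- unique(as.character(adaptation$site))
  offs <- list()
  out <- lapply(names(models), function(r) {
    m <- models[[r]]
    base <- m
    base$delta <- NULL
    pr <- local({
      b <- base
      b$delta <- stats::setNames(as.list(rep(0, length(sites))), sites)
      predict(b, adaptation)
    })
    ystd <- (adaptation[[r]] - m$y_center) / m$y_scale
    w <- shash_warp(ystd, m$warp[["a"]], m$warp[["b"]])
    resid <- w - pr$mu_warped
    delta <- vapply(sites, function(s)
      mean(resid[adaptation$site == s]), numeric(1))
    m$delta <- as.list(delta)
    m$n_adapt <- as.integer(table(factor(adaptation$site, levels = sites)))
    names(m$n_adapt) <- sites
    offs[[r]] <<- data.frame(roi = r, target_site = sites,
                             delta = unname(delta),
                             n_adapt = as.integer(table(
                               factor(adaptation$site, levels = sites))))
    m
  })
  names(out) <- names(models)
  attr(out, "offsets") <- do.call(rbind, offs)
  out
}

#' Paired within-cohort vs transfer-adapted benchmark
#'
#' Runs the full subsampling benchmark with both arms: every sampled subset
#' is used both as the within-cohort training set and as the adaptation set
#' for models pre-trained on the reference cohort, and every readout is
#' computed for both arms against the same fixed test set. A convenience
#' wrapper around [run_benchmark()] with `arms = "both"`.
#'
#' @param reference_spec [cohort_spec()] for the HC-only reference cohort.
#' @param target_spec [cohort_spec()] for the target cohort.
#' @param grid a [size_grid()].
#' @param strategies strategy labels (see [enumerate_conditions()]).
#' @param ref_offset raw-units acquisition offset of the reference cohort.
#' @param root_seed root seed.
#' @param ... passed to [run_benchmark()].
#' @return a benchmark bundle (see [run_benchmark()]); the fit-metric table
#'   gains a `diff_*` block, within-cohort minus adapted, aligned row-wise.
#' @export
transfer_benchmark <- function(reference_spec, target_spec, grid,
                               strategies = "representative",
                               ref_offset = 0.1, root_seed = 1L, ...) {
  cfg <- benchmark_config(cohort_spec = target_spec, grid = grid,
                          strategies = strategies, root_seed = root_seed,
                          arms = "both", reference_spec = reference_spec,
                          ref_offset = ref_offset, ...)
  run_benchmark(cfg)
}
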