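#' Benchmark configuration
#'
#' Bundles everything [run_benchmark()] needs: the synthetic cohort, the
#' size grid and sampling strategies, the arms to run and the root seed.
#'
#' @param cohort_spec target [cohort_spec()].
#' @param grid a [size_grid()].
#' @param strategies character vector of strategy labels (e.g.
#'   `c("representative", "left_skewed", "right_skewed",
#'   "sex_imbalanced_1_4")`).
#' @param root_seed integer; every random stage derives its seed from it.
#' @param arms `"within"` (train on the subsample), `"transfer"` (adapt
#'   pre-trained reference models with the subsample) or `"both"`.
#' @param reference_spec [cohort_spec()] of the HC-only reference cohort
#'   (required for the transfer arm).
#' @param ref_offset raw-units offset of the reference cohort relative to
#'   the target generator (acquisition shift).
#' @param train_fraction HC training fraction of the target cohort.
#' @param output_dir optional directory for resumable per-condition caching
#'   and the long-table CSVs.
#' @param classify whether to compute the SVC ROC-AUC readout per condition.
#' @return object of class `benchmark_config`.
#' @export
benchmark_config <- function(cohort_spec, grid, strategies = "representative",
                             root_seed = 1L, arms = c("within", "transfer", "both"),
                             reference_spec = NULL, ref_offset = 0.1,
                             train_fraction = 0.8, output_dir = NULL,
                             classify = TRUE) {
  arms <- match.arg(arms)
  if (arms %in% c("transfer", "both") && is.null(reference_spec))
    stop("transfer arm requires a reference_spec", call. = FALSE)
  structure(list(cohort_spec = cohort_spec, grid = grid,
                 strategies = strategies, root_seed = as.integer(root_seed),
                 arms = arms, reference_spec = reference_spec,
                 ref_offset = ref_offset, train_fraction = train_fraction,
                 output_dir = output_dir, classify = classify),
            class = "benchmark_config")
}

#' Run the subsampling benchmark
#'
#' Executes the full pipeline: generate the synthetic cohort, split it
#' (stratified, fixed test set of held-out HC plus all AD), fit the
#' full-training-set reference models, then for every condition draw the
#' training subsample, fit (and/or adapt) per-ROI models, and compute model
#' fit metrics on the HC test set, z-score errors against the full-sample
#' reference, outlier readouts and HC-vs-AD classification. Conditions are
#' cached per (arm, strategy, n, iteration) under `output_dir` and skipped
#' on rerun; per-condition failures are recorded and the run continues.
#'
#' @param config a [benchmark_config()].
#' @return a results bundle: list with `tables` (long data frames
#'   `fit_metrics`, `z_mse`, `z_mbe`, `toc`, `outliers`, `auc`), `z`
#'   (deviation matrices per arm and condition), `z_ref` (full-reference
#'   deviation matrices per arm), `test`, `pool`, `manifest` and `failures`.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "benchmark_config"))
  cache_dir <- config$output_dir
  if (!is.null(cache_dir))
    dir.create(file.path(cache_dir, "conditions"), recursive = TRUE,
               showWarnings = FALSE)

  cohort <- generate_cohort(config$cohort_spec)
  sp <- stratified_split(cohort, config$train_fraction,
                         seed = config$root_seed)
  pool <- sp$train; test <- sp$test
  rois <- roi_columns(cohort)
  groups <- test$diagnosis

  arms <- switch(config$arms, within = "within", transfer = "transfer",
                 both = c("within", "transfer"))

  full_models <- wblr_fit_rois(pool)
  z_ref <- list()
  pre <- NULL
  if ("within" %in% arms) z_ref$within <- zscore_matrix(full_models, test)
  if ("transfer" %in% arms) {
    reference <- generate_reference_cohort(config$reference_spec,
                                           config$ref_offset)
    pre <- pretrain(reference, seed = config$root_seed)
    adapted_full <- adapt_models(pre$models, pool)
    z_ref$transfer <- zscore_matrix(adapted_full, test)
  }

  conditions <- enumerate_conditions(config$grid, config$strategies,
                                     config$root_seed)
  manifest <- attr(conditions, "manifest")
  # the full-pool condition: single iteration per strategy-independent arm
  full_specs <- if (config$grid$include_full) list(full = TRUE) else list()

  tables <- list(fit_metrics = list(), z_mse = list(), z_mbe = list(),
                 toc = list(), outliers = list(), auc = list())
  zs <- list(); failures <- list()

  eval_condition <- function(train_set, arm, strategy, n, iteration) {
    models <- if (arm == "within") wblr_fit_rois(train_set)
              else adapt_models(pre$models, train_set)
    hc_test <- test[groups == "HC", , drop = FALSE]
    fm <- do.call(rbind, lapply(rois, function(r)
      cbind(roi = r, fit_metrics(models[[r]], hc_test))))
    Z <- zscore_matrix(models, test)
    msev <- z_mse(Z, z_ref[[arm]])
    mbev <- z_mbe(Z, z_ref[[arm]])
    tocv <- toc(Z)
    op <- outlier_percentages(Z, groups)
    meta <- data.frame(arm = arm, strategy = strategy, n = n,
                       iteration = iteration)
    res <- list(
      fit_metrics = cbind(meta, fm),
      z_mse = cbind(meta, data.frame(subject_id = test$subject_id,
                                     group = groups, mse_z = unname(msev))),
      z_mbe = cbind(meta, data.frame(roi = names(mbev), mbe_z = unname(mbev))),
      toc = cbind(meta, data.frame(subject_id = test$subject_id,
                                   group = groups, toc = unname(tocv))),
      outliers = cbind(meta, op),
      z = Z)
    if (config$classify) {
      cg <- classify_groups(Z, groups, seed = config$root_seed)
      res$auc <- cbind(meta, data.frame(mean_auc = cg$mean_auc))
    }
    res
  }

  run_one <- function(train_set, arm, strategy, n, iteration) {
    key <- sprintf("%s_%s_%s_%03d", arm, strategy, n, iteration)
    cache <- if (!is.null(cache_dir))
      file.path(cache_dir, "conditions", paste0(key, ".rds"))
    if (!is.null(cache_dir) && file.exists(cache)) return(readRDS(cache))
    res <- eval_condition(train_set, arm, strategy, n, iteration)
    if (!is.null(cache_dir)) saveRDS(res, cache)
    res
  }

  store <- function(res, key) {
    for (nm in names(tables))
      if (!is.null(res[[nm]])) tables[[nm]][[key]] <<- res[[nm]]
    zs[[key]] <<- res$z
  }

  for (i in seq_along(conditions)) {
    cs <- conditions[[i]]
    lab <- manifest$strategy[i]
    for (arm in arms) {
      key <- sprintf("%s_%s_%d_%03d", arm, lab, cs$n, cs$iteration)
      out <- tryCatch({
        smp <- draw_sample(pool, cs)
        run_one(smp, arm, lab, cs$n, cs$iteration)
      }, error = function(e) e)
      if (inherits(out, "error")) {
        failures[[key]] <- conditionMessage(out)
      } else store(out, key)
    }
  }
  if (length(full_specs)) {
    for (arm in arms) {
      key <- sprintf("%s_full_%d_001", arm, nrow(pool))
      out <- tryCatch(run_one(pool, arm, "full", nrow(pool), 1L),
                      error = function(e) e)
      if (inherits(out, "error")) failures[[key]] <- conditionMessage(out)
      else store(out, key)
    }
  }

  tables <- lapply(tables, function(x)
    if (length(x)) { r <- do.call(rbind, x); rownames(r) <- NULL; r } else NULL)

  bundle <- list(config = config, tables = tables, z = zs, z_ref = z_ref,
                 test = test, pool = pool, full_models = full_models,
                 pretrained = pre, manifest = manifest, failures = failures)
  class(bundle) <- "normbench_run"
  if (!is.null(cache_dir)) {
    for (nm in names(tables))
      if (!is.null(tables[[nm]]))
        utils::write.csv(tables[[nm]],
                         file.path(cache_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
    jsonlite::write_json(
      list(root_seed = config$root_seed, strategies = config$strategies,
           sizes = config$grid$sizes, arms = config$arms,
           n_pool = nrow(pool), n_test = nrow(test),
           failures = failures),
      file.path(cache_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  bundle
}

#' @export
print.normbench_run <- function(x, ...) {
  cat("normbench benchmark run\n")
  cat(sprintf("  arms: %s; strategies: %s\n", x$config$arms,
              paste(x$config$strategies, collapse = ", ")))
  cat(sprintf("  pool %d HC, test %d (%d HC / %d AD)\n", nrow(x$pool),
              nrow(x$test), sum(x$test$diagnosis == "HC"),
              sum(x$test$diagnosis == "AD")))
  cat(sprintf("  conditions evaluated: %d; failures: %d\n",
              length(x$z), length(x$failures)))
  invisible(x)
}

#' Per-ROI ICC of deviation scores across iterations
#'
#' For each (arm, strategy, n) with at least two iterations, stacks the HC
#' test-set deviation scores across iterations and computes [icc_2_1()] per
#' ROI.
#'
#' @param bundle a [run_benchmark()] bundle.
#' @return long data frame `arm`, `strategy`, `n`, `roi`, `icc`.
#' @export
benchmark_icc <- function(bundle) {
  keys <- names(bundle$z)
  info <- do.call(rbind, lapply(keys, function(k) {
    # key format: arm_strategy_n_iter with strategy possibly containing '_'
    m <- regmatches(k, regexec("^(within|transfer)_(.+)_([0-9]+)_([0-9]+)$", k))[[1]]
    data.frame(key = k, arm = m[2], strategy = m[3],
               n = as.integer(m[4]), iteration = as.integer(m[5]))
  }))
  hc <- bundle$test$diagnosis == "HC"
  out <- list()
  for (grp in split(info, interaction(info$arm, info$strategy, info$n, drop = TRUE))) {
    if (nrow(grp) < 2) next
    rois <- colnames(bundle$z[[grp$key[1]]])
    for (r in rois) {
      M <- vapply(grp$key, function(k) bundle$z[[k]][hc, r], numeric(sum(hc)))
      out[[length(out) + 1L]] <- data.frame(
        arm = grp$arm[1], strategy = grp$strategy[1], n = grp$n[1],
        roi = r, icc = icc_2_1(M))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Condition-level z-error summaries with 3xIQR exclusion
#'
#' Summarizes per-subject z-score MSE per condition after dropping values
#' outside `[Q1 - 3 IQR, Q3 + 3 IQR]` (computed over the pooled per-subject
#' values of that condition).
#'
#' @param bundle a [run_benchmark()] bundle.
#' @return data frame `arm`, `strategy`, `n`, `iteration`, `group`,
#'   `mean_mse`, `n_kept`, `n_dropped`.
#' @export
summarize_z_mse <- function(bundle) {
  zm <- bundle$tables$z_mse
  out <- list()
  for (cond in split(zm, interaction(zm$arm, zm$strategy, zm$n, zm$iteration,
                                     drop = TRUE))) {
    keep <- iqr_keep(cond$mse_z)
    for (g in unique(cond$group)) {
      sel <- keep & cond$group == g
      out[[length(out) + 1L]] <- data.frame(
        arm = cond$arm[1], strategy = cond$strategy[1], n = cond$n[1],
        iteration = cond$iteration[1], group = g,
        mean_mse = mean(cond$mse_z[sel]),
        n_kept = sum(sel), n_dropped = sum(cond$group == g) - sum(sel))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
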