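# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(build)
  .fixtures[[name]]
}

# mid-sized single-site cohort + split, used by several files
small_cohort <- function() fixture("small_cohort", {
  spec <- cohort_spec(n_hc = 600, n_ad = 80, n_rois = 3, seed = 11)
  coh <- generate_cohort(spec)
  c(list(spec = spec, cohort = coh), stratified_split(coh, 0.8, seed = 11))
})

# a fitted model on the small cohort
small_model <- function() fixture("small_model", {
  sc <- small_cohort()
  wblr(roi_001 ~ age + sex + site, sc$train)
})

# identity-warp (plain Gaussian) cohort for closed-form checks
gaussian_cohort <- function() fixture("gaussian_cohort", {
  spec <- cohort_spec(n_hc = 500, n_ad = 0, n_rois = 1, seed = 21,
                      warp_true = c(a = 0, b = 1))
  generate_cohort(spec)
})

# desk-scale benchmark: 30 ROIs, sizes {10,25,50,100,200}, 3 iterations,
# 4 strategies, both arms, fixed root seed
desk_benchmark <- function() fixture("desk_benchmark", {
  root <- 1L
  target <- cohort_spec(n_hc = 865, n_ad = 167, n_rois = 30, seed = root)
  reference <- cohort_spec(n_hc = 5000, n_ad = 0, n_rois = 30, seed = root,
                           sites = c(ref1 = 0, ref2 = 0.05, ref3 = -0.05))
  cfg <- benchmark_config(
    cohort_spec = target,
    grid = size_grid(sizes = c(10L, 25L, 50L, 100L, 200L),
                     iterations_per_size = 3L),
    strategies = c("representative", "left_skewed", "right_skewed",
                   "sex_imbalanced_1_4"),
    root_seed = root, arms = "both", reference_spec = reference,
    ref_offset = 0.1, classify = TRUE)
  t0 <- Sys.time()
  bundle <- run_benchmark(cfg)
  attr(bundle, "elapsed_min") <-
    as.numeric(difftime(Sys.time(), t0, units = "mins"))
  bundle
})
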