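test_that("identical spec and seed give bit-identical cohorts", {
  spec <- cohort_spec(n_hc = 80, n_ad = 20, n_rois = 4, seed = 5)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  attr(a, "truth") <- attr(b, "truth") <- NULL
  attr(a, "spec") <- attr(b, "spec") <- NULL
  expect_identical(a, b)
})

test_that("cohort respects the demographic envelope", {
  spec <- cohort_spec(n_hc = 865, n_ad = 167, n_rois = 2,
                      sex_fraction_female = 0.58, seed = 8)
  coh <- generate_cohort(spec)
  expect_equal(sum(coh$diagnosis == "HC"), 865)
  expect_equal(sum(coh$diagnosis == "AD"), 167)
  expect_true(all(coh$age >= 45 & coh$age <= 82))
  # female fraction within 3 binomial SDs of 0.58
  fr <- mean(coh$sex == "F")
  expect_lt(abs(fr - 0.58), 3 * sqrt(0.58 * 0.42 / nrow(coh)))
  expect_true(all(is.finite(as.matrix(coh[roi_columns(coh)]))))
})

test_that("empirical sex fraction obeys the law of large numbers", {
  spec <- cohort_spec(n_hc = 10000, n_ad = 0, n_rois = 1,
                      sex_fraction_female = 0.58, seed = 13)
  coh <- generate_cohort(spec)
  expect_lt(abs(mean(coh$sex == "F") - 0.58),
            3 * sqrt(0.58 * 0.42 / 10000))
})

test_that("with noise off and identity warp the response is the deterministic mean curve", {
  spec <- cohort_spec(n_hc = 60, n_ad = 0, n_rois = 1, seed = 3,
                      noise_precision_true = 1e8, warp_true = c(a = 0, b = 1))
  coh <- generate_cohort(spec)
  tr <- attr(coh, "truth")
  # recompute the curve independently from the stored ground truth
  Phi <- build_design(coh, tr$basis)
  r <- tr$rois[[1]]
  eta <- r$calib[["A"]] + r$calib[["B"]] * drop(Phi %*% r$weights)
  expect_equal(coh$roi_001, r$center + r$scale * eta, tolerance = 1e-3)
})

test_that("invalid generator parameters are rejected", {
  expect_error(cohort_spec(noise_precision_true = 0), "noise")
  expect_error(cohort_spec(warp_true = c(0, -1)), "b > 0")
  expect_error(cohort_spec(n_rois = 3, roi_names = "one"), "roi_names")
  expect_error(cohort_spec(n_hc = -1), "n_hc")
})

test_that("AD atrophy recovers the configured Cohen's d", {
  # identity warp and age-matched AD so the warped-space shift is exactly a
  # standardized mean difference in response units
  spec <- cohort_spec(n_hc = 2000, n_ad = 2000, n_rois = 2, seed = 17,
                      warp_true = c(a = 0, b = 1), ad_effect = 1.0,
                      mtl_rois = "roi_001", ad_age_bias = FALSE)
  coh <- generate_cohort(spec)
  fit <- lm(roi_001 ~ age + sex + diagnosis, data = coh)
  sd_res <- summary(fit)$sigma
  d_hat <- abs(coef(fit)[["diagnosisHC"]]) / sd_res  # HC - AD difference
  expect_lt(abs(d_hat - 1.0), 0.1)
  # ROI without atrophy shows no group effect
  fit0 <- lm(roi_002 ~ age + sex + diagnosis, data = coh)
  expect_lt(abs(coef(fit0)[["diagnosisHC"]]) / summary(fit0)$sigma, 0.1)
})

test_that("reference cohort with zero offset shares the target's means", {
  tgt <- cohort_spec(n_hc = 1500, n_ad = 0, n_rois = 2, seed = 9)
  ref_spec <- cohort_spec(n_hc = 3000, n_ad = 0, n_rois = 2, seed = 9)
  tgt_tab <- generate_cohort(tgt)
  ref_tab <- generate_reference_cohort(ref_spec, offset = 0)
  for (r in roi_columns(tgt_tab)) {
    se <- sqrt(var(tgt_tab[[r]]) / 1500 + var(ref_tab[[r]]) / 3000)
    expect_lt(abs(mean(tgt_tab[[r]]) - mean(ref_tab[[r]])), 4 * se)
  }
})

test_that("a raw offset shifts every value exactly when noise is off", {
  base <- cohort_spec(n_hc = 50, n_ad = 0, n_rois = 1, seed = 4,
                      noise_precision_true = 1e8, warp_true = c(a = 0, b = 1))
  tgt <- generate_cohort(base)
  ref <- generate_reference_cohort(base, offset = 0.1)
  expect_equal(ref$roi_001, tgt$roi_001 + 0.1, tolerance = 1e-12)
})

test_that("least squares on generated data recovers the reference offset", {
  base <- cohort_spec(n_hc = 4000, n_ad = 0, n_rois = 1, seed = 6,
                      warp_true = c(a = 0, b = 1))
  tgt <- generate_cohort(base)
  ref <- generate_reference_cohort(base, offset = 0.1)
  b_t <- coef(lm(roi_001 ~ age + sex, tgt))
  b_r <- coef(lm(roi_001 ~ age + sex, ref))
  expect_lt(abs((b_r[["(Intercept)"]] - b_t[["(Intercept)"]]) - 0.1), 0.03)
})

test_that("a reference cohort must be HC-only", {
  expect_error(
    generate_reference_cohort(cohort_spec(n_hc = 10, n_ad = 5, n_rois = 1)),
    "HC-only")
})

test_that("stratified split partitions the cohort and holds out all AD", {
  sc <- small_cohort()
  sp <- stratified_split(sc$cohort, 0.8, seed = 2)
  expect_equal(sort(c(sp$train$subject_id, sp$test$subject_id)),
               sort(sc$cohort$subject_id))
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)
  expect_true(all(sp$train$diagnosis == "HC"))
  expect_equal(sum(sp$test$diagnosis == "AD"), sum(sc$cohort$diagnosis == "AD"))
})

test_that("a single homogeneous stratum splits 80/20 exactly", {
  tab <- data.frame(subject_id = sprintf("s%03d", 1:100),
                    age = rep(60.5, 100), sex = "F", site = "A",
                    diagnosis = "HC", roi_001 = rnorm(100))
  sp <- stratified_split(tab, 0.8, seed = 1)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$test), 20)
})

test_that("865 HC at fraction 0.8 yield 692 +/- 1 training subjects", {
  spec <- cohort_spec(n_hc = 865, n_ad = 0, n_rois = 1, seed = 10)
  sp <- stratified_split(generate_cohort(spec), 0.8, seed = 10)
  expect_lte(abs(nrow(sp$train) - 692), 1)
})

test_that("invalid train fractions are rejected", {
  sc <- small_cohort()
  expect_error(stratified_split(sc$cohort, 0), "train_fraction")
  expect_error(stratified_split(sc$cohort, 1), "train_fraction")
})

test_that("cohorts survive a CSV round trip with their sidecar", {
  spec <- cohort_spec(n_hc = 30, n_ad = 10, n_rois = 2, seed = 12)
  coh <- generate_cohort(spec)
  path <- file.path(withr::local_tempdir(), "cohort.csv")
  write_cohort(coh, path)
  expect_true(file.exists(paste0(path, ".spec.json")))
  back <- read_cohort(path)
  expect_equal(back$age, coh$age, tolerance = 1e-10)
  expect_equal(back$roi_001, coh$roi_001, tolerance = 1e-10)
  expect_equal(attr(back, "spec")$seed, spec$seed)
})

test_that("the 167-ROI parcellation has 148 cortical and 19 subcortical names", {
  nm <- default_roi_names(167)
  expect_length(nm, 167)
  expect_equal(sum(grepl("^ctx_", nm)), 148)
  expect_equal(sum(!grepl("^ctx_", nm)), 19)
  expect_true(all(c("Left_Hippocampus", "Right_Amygdala") %in% nm))
})
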