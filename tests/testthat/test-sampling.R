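make_pool <- function(n = 692, seed = 30) {
  normbench:::with_seed(seed, data.frame(
    subject_id = sprintf("p%04d", seq_len(n)),
    age = runif(n, 45, 82),
    sex = sample(c("F", "M"), n, replace = TRUE),
    site = "A", diagnosis = "HC",
    roi_001 = rnorm(n)))
}

test_that("quantile bins divide evenly and handle remainders and ties", {
  b <- quantile_bins(runif(100, 40, 80), 10)
  expect_equal(as.integer(table(b)), rep(10L, 10))
  b2 <- quantile_bins(runif(101, 40, 80), 10)
  expect_equal(sort(as.integer(table(b2))), c(rep(10L, 9), 11L))
  b3 <- quantile_bins(rep(60, 30), 10)        # all ages identical
  expect_equal(as.integer(table(b3)), rep(3L, 10))
  expect_identical(b3, quantile_bins(rep(60, 30), 10))
  expect_error(quantile_bins(1:5, 10), "fewer")
  # bins are ordered by age
  ages <- runif(200, 45, 82)
  b4 <- quantile_bins(ages, 10)
  expect_true(max(ages[b4 == 1]) <= min(ages[b4 == 10]))
})

test_that("representative sampling hits exact bin and sex arithmetic", {
  pool <- make_pool(300)
  s <- representative_sample(pool, sampling_spec("representative", n = 10, seed = 3))
  expect_equal(nrow(s), 10)
  bins <- quantile_bins(pool$age, 10)
  sel_bins <- bins[match(s$subject_id, pool$subject_id)]
  expect_equal(as.integer(table(factor(sel_bins, levels = 1:10))), rep(1L, 10))
  s2 <- representative_sample(pool, sampling_spec("representative", n = 100, seed = 3))
  expect_equal(sum(s2$sex == "F"), 50)
  expect_error(representative_sample(pool, sampling_spec("representative",
                                                         n = 400, seed = 1)))
})

test_that("representative samples preserve the pool age distribution", {
  pool <- make_pool(692)
  breaks <- quantile(pool$age, seq(0, 1, 0.1))
  p_pool <- rep(0.1, 10)
  pvals <- vapply(1:10, function(s) {
    smp <- representative_sample(pool, sampling_spec("representative",
                                                     n = 600, seed = s))
    counts <- table(cut(smp$age, breaks, include.lowest = TRUE))
    suppressWarnings(chisq.test(counts, p = p_pool)$p.value)
  }, numeric(1))
  expect_true(all(pvals > 0.01))
})

test_that("beta bin weights match the closed-form density ratio", {
  # Beta(2,5) pdf is 30 x (1-x)^4; at midpoints 0.05 and 0.95 the ratio is 19^3
  w <- dbeta(c(0.05, 0.95), 2, 5)
  expect_equal(w[1] / w[2], 19^3, tolerance = 1e-10)
  expect_equal(w[1], 30 * 0.05 * 0.95^4, tolerance = 1e-12)
  # Beta(5,2) mirrors Beta(2,5) across bins
  mid <- (1:10 - 0.5) / 10
  expect_equal(dbeta(mid, 5, 2), rev(dbeta(mid, 2, 5)), tolerance = 1e-12)
})

test_that("skewed sampling shifts the age distribution in the right direction", {
  pool <- make_pool(692)
  mleft <- mean(vapply(1:20, function(s)
    mean(skewed_sample(pool, sampling_spec("left_skewed", n = 200,
                                           seed = s))$age), numeric(1)))
  mright <- mean(vapply(1:20, function(s)
    mean(skewed_sample(pool, sampling_spec("right_skewed", n = 200,
                                           seed = s))$age), numeric(1)))
  expect_lt(mleft, mean(pool$age) - 2)
  expect_gt(mright, mean(pool$age) + 2)
  # representative tracks the pool more closely than either skewed scheme
  ks <- function(x) suppressWarnings(ks.test(x, pool$age)$statistic)
  ks_rep <- mean(vapply(1:10, function(s)
    ks(representative_sample(pool, sampling_spec("representative", n = 200,
                                                 seed = s))$age), numeric(1)))
  ks_skew <- mean(vapply(1:10, function(s)
    ks(skewed_sample(pool, sampling_spec("left_skewed", n = 200,
                                         seed = s))$age), numeric(1)))
  expect_lt(ks_rep, ks_skew)
})

test_that("skewed sampling keeps sizes exact when favored bins run dry", {
  pool <- make_pool(250)
  s <- skewed_sample(pool, sampling_spec("left_skewed", n = 240, seed = 2))
  expect_equal(nrow(s), 240)
  expect_length(unique(s$subject_id), 240)
})

test_that("sex-imbalanced sampling follows the rounding rule", {
  pool <- make_pool(500)
  s <- sex_imbalanced_sample(pool, sampling_spec("sex_imbalanced", n = 10,
                                                 sex_ratio = c(4, 1), seed = 1))
  expect_equal(as.integer(table(factor(s$sex, levels = c("F", "M")))), c(8L, 2L))
  s2 <- sex_imbalanced_sample(pool, sampling_spec("sex_imbalanced", n = 11,
                                                  sex_ratio = c(1, 10), seed = 1))
  expect_equal(as.integer(table(factor(s2$sex, levels = c("F", "M")))), c(1L, 10L))
  s3 <- sex_imbalanced_sample(pool, sampling_spec("sex_imbalanced", n = 100,
                                                  sex_ratio = c(1, 1), seed = 1))
  expect_lte(abs(sum(s3$sex == "F") - sum(s3$sex == "M")), 1)
  # deficit errors name the missing sex
  allM <- make_pool(50); allM$sex <- "M"
  expect_error(sex_imbalanced_sample(allM, sampling_spec("sex_imbalanced",
                                                         n = 20, sex_ratio = c(10, 1), seed = 1)),
               "insufficient F")
})

test_that("samples never duplicate subjects and stay inside the pool", {
  pool <- make_pool(400)
  for (st in c("representative", "left_skewed", "right_skewed")) {
    s <- draw_sample(pool, sampling_spec(st, n = 123, seed = 7))
    expect_equal(anyDuplicated(s$subject_id), 0L)
    expect_true(all(s$subject_id %in% pool$subject_id))
    expect_equal(nrow(s), 123)
  }
})

test_that("draws are deterministic under the condition seed", {
  pool <- make_pool(400)
  sp <- sampling_spec("left_skewed", n = 77, seed = 19)
  expect_identical(draw_sample(pool, sp), draw_sample(pool, sp))
})

test_that("the default grid enumerates the published size ladder", {
  g <- size_grid()
  expect_length(g$sizes, 48)                    # 40 sizes of 5..200 + 8 more
  expect_equal(g$sizes[1:3], c(5L, 10L, 15L))
  expect_equal(tail(g$sizes, 2), c(550L, 600L))
  conds <- enumerate_conditions(size_grid(sizes = 50L,
                                          iterations_per_size = 10L),
                                "representative")
  expect_length(conds, 10)
  # seeds pairwise distinct over the full default grid
  all_conds <- enumerate_conditions(g, c("representative", "left_skewed",
                                         "right_skewed", "sex_imbalanced_1_10"))
  seeds <- vapply(all_conds, function(s) s$seed, integer(1))
  expect_equal(anyDuplicated(seeds), 0L)
  m <- attr(all_conds, "manifest")
  expect_equal(nrow(m), 48 * 10 * 4)
  # ratio labels parse into the sampling spec
  imb <- all_conds[[length(all_conds)]]
  expect_equal(imb$strategy, "sex_imbalanced")
  expect_equal(imb$sex_ratio, c(1, 10))
})
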