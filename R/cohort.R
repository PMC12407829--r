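#' Specification of a synthetic cohort
#'
#' Declares the ground truth of a seed-reproducible synthetic cohort emulating
#' a structural-MRI ageing study: healthy controls (HC) and Alzheimer's
#' disease (AD) subjects aged 45-82, sex and site covariate effects, smooth
#' age decline of each regional measure, and sinh-arcsinh-shaped residuals.
#' The generating basis is the same cubic B-spline basis used by [wblr()], so
#' model-true simulations and parameter recovery are well-posed.
#'
#' The generator works in warped (Gaussian) space: a latent response
#' \eqn{\eta = \phi(x)^\top w + \mathrm{site} + \varepsilon},
#' \eqn{\varepsilon \sim N(0, 1/\beta)}, is passed through a deterministic
#' per-ROI affine calibration (so the emitted standardized response has
#' population mean ~0 and SD ~1, making the warp identifiable when the model
#' standardizes by training moments) and then through the inverse warp
#' \eqn{W^{-1}(\cdot; a, b)}. AD atrophy is a mean shift in warped space of
#' `ad_effect` generating residual SDs, applied only to designated
#' "medial-temporal-like" ROIs. The effective noise precision after
#' calibration, `beta_true / B^2`, is reported in the ground-truth attribute.
#'
#' @param n_hc,n_ad numbers of HC and AD subjects.
#' @param age_min,age_max age range in years.
#' @param sex_fraction_female probability that a subject is female.
#' @param sites named numeric vector of per-site warped-space mean offsets
#'   (one entry per site; default a single site with offset 0).
#' @param n_rois number of regions; `roi_names` defaults to
#'   [default_roi_names()] of this length.
#' @param roi_names character vector of region names.
#' @param true_weights optional list (one numeric vector per ROI) of
#'   generating weights on the design columns; auto-generated smooth age
#'   declines when `NULL`.
#' @param noise_precision_true latent noise precision \eqn{\beta > 0}.
#' @param warp_true length-2 vector `(a, b)` of the generating SHASH warp;
#'   `b > 0`. The default is mildly skewed/kurtotic so the warp is
#'   identifiable.
#' @param ad_effect Cohen's d of AD atrophy in warped residual units; a
#'   scalar is applied to the medial-temporal-like ROIs (others 0), or give a
#'   full per-ROI vector.
#' @param mtl_rois optional character vector naming the atrophy ROIs;
#'   defaults to hippocampus/amygdala-like names, else the first 10% of ROIs.
#' @param age_density `"uniform"` (default) or `"older"` (right-heavy, to
#'   mimic ageing-cohort recruitment).
#' @param ad_age_bias if `TRUE` (default) AD ages are drawn right-heavy over
#'   `[max(age_min, 50), age_max]`; if `FALSE` AD ages follow the HC density.
#' @param warp_offset constant added to the calibrated warped-space response
#'   of every subject (used to emulate an acquisition shift that is exactly
#'   constant in warped space; see [adapt_models()]).
#' @param seed integer seed; identical spec + seed gives bit-identical output.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_hc = 865, n_ad = 167, age_min = 45, age_max = 82,
                        sex_fraction_female = 0.58, sites = c(site1 = 0),
                        n_rois = 30, roi_names = NULL, true_weights = NULL,
                        noise_precision_true = 4, warp_true = c(a = 0.3, b = 1.4),
                        ad_effect = 1.5, mtl_rois = NULL,
                        age_density = c("uniform", "older"),
                        ad_age_bias = TRUE, warp_offset = 0, seed = 1L) {
  age_density <- match.arg(age_density)
  if (n_hc < 0 || n_ad < 0) stop("n_hc and n_ad must be >= 0", call. = FALSE)
  if (n_rois < 1) stop("n_rois must be >= 1", call. = FALSE)
  if (noise_precision_true <= 0)
    stop("noise_precision_true must be > 0", call. = FALSE)
  if (length(warp_true) != 2 || warp_true[2] <= 0)
    stop("warp_true must be (a, b) with b > 0", call. = FALSE)
  if (age_max <= age_min) stop("age_max must exceed age_min", call. = FALSE)
  roi_names <- roi_names %||% default_roi_names(n_rois)
  if (length(roi_names) < 1) stop("empty ROI list", call. = FALSE)
  if (length(roi_names) != n_rois)
    stop("roi_names length must equal n_rois", call. = FALSE)
  if (is.null(names(sites))) names(sites) <- paste0("site", seq_along(sites))
  if (is.null(mtl_rois)) {
    mtl_rois <- roi_names[grepl("Hippocampus|Amygdala|parahip|entorhinal",
                                roi_names, ignore.case = TRUE)]
    if (!length(mtl_rois))
      mtl_rois <- roi_names[seq_len(max(1L, ceiling(0.1 * n_rois)))]
  }
  if (length(ad_effect) == 1L) {
    ad <- stats::setNames(rep(0, n_rois), roi_names)
    ad[mtl_rois] <- ad_effect
    ad_effect <- ad
  } else {
    if (length(ad_effect) != n_rois)
      stop("ad_effect must be scalar or one value per ROI", call. = FALSE)
    ad_effect <- stats::setNames(as.numeric(ad_effect), roi_names)
  }
  if (any(ad_effect < 0)) stop("ad_effect must be >= 0", call. = FALSE)
  structure(list(
    n_hc = as.integer(n_hc), n_ad = as.integer(n_ad),
    age_min = age_min, age_max = age_max,
    sex_fraction_female = sex_fraction_female, sites = sites,
    n_rois = as.integer(n_rois), roi_names = roi_names,
    true_weights = true_weights,
    noise_precision_true = noise_precision_true,
    warp_true = stats::setNames(as.numeric(warp_true), c("a", "b")),
    ad_effect = ad_effect, mtl_rois = mtl_rois,
    age_density = age_density, ad_age_bias = ad_age_bias,
    warp_offset = warp_offset, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Default ROI names
#'
#' For `n = 167` returns the full emulated parcellation: 148 cortical names
#' (74 per hemisphere, Destrieux-style) generated programmatically plus 19
#' subcortical (ASEG-style) names, including the hippocampus and amygdala
#' which carry the AD atrophy effect. Other lengths get generic `roi_###`
#' names.
#'
#' @param n number of ROIs.
#' @return character vector of length `n`.
#' @export
default_roi_names <- function(n) {
  if (n == 167L) {
    cortical <- c(sprintf("ctx_lh_roi%03d", 1:74), sprintf("ctx_rh_roi%03d", 1:74))
    subcortical <- c(
      "Left_Thalamus", "Right_Thalamus", "Left_Caudate", "Right_Caudate",
      "Left_Putamen", "Right_Putamen", "Left_Pallidum", "Right_Pallidum",
      "Left_Hippocampus", "Right_Hippocampus", "Left_Amygdala",
      "Right_Amygdala", "Left_Accumbens_area", "Right_Accumbens_area",
      "Left_VentralDC", "Right_VentralDC", "Brain_Stem",
      "Left_Cerebellum_Cortex", "Right_Cerebellum_Cortex")
    c(cortical, subcortical)
  } else {
    sprintf("roi_%03d", seq_len(n))
  }
}

# Deterministic per-ROI ground truth (weights, units, calibration), derived
# from a seed stream separate from the demographic draws so that cohorts of
# different sizes generated from the same seed share their generating curves.
cohort_truth <- function(spec) {
  frame <- data.frame(
    age = seq(spec$age_min, spec$age_max, length.out = 61),
    sex = "F", site = names(spec$sites)[1L])
  basis <- basis_prepare(basis_spec(), frame)
  basis$site_levels <- names(spec$sites)
  grid_F <- build_design(frame, basis)
  frame$sex <- "M"
  grid_M <- build_design(frame, basis)
  dcols <- colnames(grid_F)
  nspl <- sum(grepl("^bspl", dcols))
  subcortical <- grepl("^(Left|Right|Brain)_", spec$roi_names)

  truth <- with_seed(spec$seed + 1000003L, {
    lapply(seq_len(spec$n_rois), function(r) {
      if (!is.null(spec$true_weights)) {
        w <- spec$true_weights[[r]]
        if (length(w) != length(dcols))
          stop("true_weights[[", r, "]] must have ", length(dcols),
               " entries (design columns: ", paste(dcols, collapse = ", "),
               ")", call. = FALSE)
        w <- stats::setNames(as.numeric(w), dcols)
      } else {
        # smooth, mostly linear age decline in warped space plus a small
        # curvature term; projected onto the spline basis
        slope <- stats::runif(1, 0.35, 0.55)
        curv <- stats::runif(1, 0.05, 0.15)
        xs <- (frame$age - basis$age_center) / basis$age_scale
        target <- -slope * xs - curv * xs^2
        Xa <- grid_F[, c(1L, seq_len(nspl) + 1L), drop = FALSE]
        wa <- qr.solve(Xa, target)
        w <- stats::setNames(rep(0, length(dcols)), dcols)
        w[c(1L, seq_len(nspl) + 1L)] <- wa
        if ("sexM" %in% dcols) w["sexM"] <- stats::runif(1, 0.05, 0.25)
      }
      if (subcortical[r]) {
        center <- stats::runif(1, 1500, 8000); scale <- 0.12 * center
      } else {
        center <- stats::runif(1, 1.8, 3.2); scale <- stats::runif(1, 0.1, 0.2)
      }
      list(weights = w, center = center, scale = scale)
    })
  })
  names(truth) <- spec$roi_names

  # deterministic affine calibration in warped space (quadrature, no RNG)
  a <- spec$warp_true[["a"]]; b <- spec$warp_true[["b"]]
  beta <- spec$noise_precision_true
  age_w <- if (spec$age_density == "older") {
    u <- seq(0.005, 0.995, length.out = 61)
    stats::dbeta(u, 2.5, 1.5)
  } else rep(1, 61)
  age_w <- age_w / sum(age_w)
  noise_nodes <- stats::qnorm((1:17 - 0.5) / 17) / sqrt(beta)
  for (r in seq_len(spec$n_rois)) {
    w <- truth[[r]]$weights
    mF <- drop(grid_F %*% w); mM <- drop(grid_M %*% w)
    pf <- spec$sex_fraction_female
    m_nodes <- c(mF, mM)
    m_w <- c(age_w * pf, age_w * (1 - pf))
    site_off <- rep(spec$sites, each = 1)
    m_nodes <- as.vector(outer(m_nodes, site_off, `+`))
    m_w <- rep(m_w * (1 / length(site_off)), times = length(site_off))
    eta <- as.vector(outer(m_nodes, noise_nodes, `+`))
    wts <- rep(m_w / length(noise_nodes), times = length(noise_nodes))
    m0 <- sum(wts * eta); s0 <- sqrt(sum(wts * (eta - m0)^2))
    obj <- function(p) {
      u <- shash_inverse(p[1] + exp(p[2]) * eta, a, b)
      mu <- sum(wts * u)
      su <- sqrt(sum(wts * (u - mu)^2))
      mu^2 + (su - 1)^2
    }
    opt <- stats::optim(c(-m0 / s0, log(1 / s0)), obj,
                        control = list(reltol = 1e-10, maxit = 500))
    A <- opt$par[1]; B <- exp(opt$par[2])
    truth[[r]]$calib <- c(A = A, B = B)
    truth[[r]]$beta_effective <- beta / B^2
    truth[[r]]$ad_shift_warped <- spec$ad_effect[[r]] * B / sqrt(beta)
  }
  list(basis = basis, rois = truth)
}

#' Generate a synthetic cohort
#'
#' Draws demographics and regional measures according to a [cohort_spec()].
#' HC ages follow the configured density over `[age_min, age_max]`; sex is
#' binomial with the configured female fraction; sites are equiprobable. See
#' [cohort_spec()] for the response model. The returned data frame carries
#' the spec and the full generating ground truth as attributes `"spec"` and
#' `"truth"` (used by parameter-recovery tests and written to the sidecar by
#' [write_cohort()]).
#'
#' @param spec a [cohort_spec()].
#' @return data frame with columns `subject_id`, `age`, `sex`, `site`,
#'   `diagnosis` and one column per ROI.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  truth <- cohort_truth(spec)
  n <- spec$n_hc + spec$n_ad
  a <- spec$warp_true[["a"]]; b <- spec$warp_true[["b"]]
  beta <- spec$noise_precision_true

  with_seed(spec$seed, {
    draw_age <- function(k, density, lo, hi) {
      if (k == 0L) return(numeric(0))
      u <- switch(density,
                  uniform = stats::runif(k),
                  older = stats::rbeta(k, 2.5, 1.5),
                  adbias = stats::rbeta(k, 3, 1.3))
      lo + u * (hi - lo)
    }
    age_hc <- draw_age(spec$n_hc, spec$age_density, spec$age_min, spec$age_max)
    if (spec$ad_age_bias) {
      age_ad <- draw_age(spec$n_ad, "adbias",
                         max(spec$age_min, 50), spec$age_max)
    } else {
      age_ad <- draw_age(spec$n_ad, spec$age_density,
                         spec$age_min, spec$age_max)
    }
    tab <- data.frame(
      subject_id = sprintf("sub-%05d", seq_len(n)),
      age = c(age_hc, age_ad),
      sex = ifelse(stats::rbinom(n, 1, spec$sex_fraction_female) == 1, "F", "M"),
      site = sample(names(spec$sites), n, replace = TRUE),
      diagnosis = rep(c("HC", "AD"), c(spec$n_hc, spec$n_ad)),
      stringsAsFactors = FALSE)
    Phi <- build_design(tab, truth$basis)
    site_off <- spec$sites[tab$site]
    is_ad <- tab$diagnosis == "AD"
    for (r in seq_len(spec$n_rois)) {
      tr <- truth$rois[[r]]
      eta0 <- drop(Phi %*% tr$weights) + site_off +
        stats::rnorm(n, 0, 1 / sqrt(beta))
      eta <- tr$calib[["A"]] + tr$calib[["B"]] * eta0 + spec$warp_offset
      eta[is_ad] <- eta[is_ad] - tr$ad_shift_warped
      tab[[spec$roi_names[r]]] <- tr$center + tr$scale *
        shash_inverse(eta, a, b)
    }
    attr(tab, "spec") <- spec
    attr(tab, "truth") <- truth
    tab
  })
}

#' Generate a large HC-only reference cohort with a systematic offset
#'
#' Emulates a large multi-site reference dataset whose per-ROI means sit a
#' constant `offset` (raw units) above the target generator's mean curves,
#' all other generating parameters shared — the acquisition-shift situation
#' that motivates transfer adaptation.
#'
#' @param spec a [cohort_spec()] with `n_ad = 0`.
#' @param offset constant added to every ROI value.
#' @return cohort data frame (see [generate_cohort()]).
#' @export
generate_reference_cohort <- function(spec, offset = 0) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_ad != 0)
    stop("reference cohort is HC-only by construction (n_ad must be 0)",
         call. = FALSE)
  tab <- generate_cohort(spec)
  for (r in spec$roi_names) tab[[r]] <- tab[[r]] + offset
  attr(tab, "offset") <- offset
  tab
}

#' Stratified train/test split
#'
#' Splits the healthy controls into a training fraction stratified jointly on
#' site, sex and half-open 5-year age bins anchored at the cohort's minimum
#' age; the test set is the remaining HC plus every AD subject. Strata with
#' no subjects are skipped; within a stratum the training count is
#' `round(train_fraction * n)`.
#'
#' @param table cohort data frame.
#' @param train_fraction fraction of HC per stratum assigned to training.
#' @param age_bin_width bin width in years (default 5).
#' @param seed integer seed for the within-stratum draw.
#' @return list with elements `train` and `test` (disjoint, union = table).
#' @export
stratified_split <- function(table, train_fraction = 0.8, age_bin_width = 5,
                             seed = 1L) {
  stopifnot_scalar_prob(train_fraction, "train_fraction")
  hc <- which(table$diagnosis == "HC")
  if (!length(hc)) stop("no HC subjects to split", call. = FALSE)
  spec <- attr(table, "spec")
  anchor <- if (!is.null(spec)) spec$age_min else min(table$age)
  bin <- floor((table$age[hc] - anchor) / age_bin_width)
  stratum <- interaction(table$site[hc], table$sex[hc], bin, drop = TRUE)
  train_idx <- with_seed(seed, {
    unlist(lapply(split(hc, stratum), function(idx) {
      k <- round(train_fraction * length(idx))
      if (k <= 0) return(integer(0))
      if (k >= length(idx)) return(idx)
      sample(idx, k)
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(nrow(table)), train_idx)
  out <- list(train = table[train_idx, , drop = FALSE],
              test = table[test_idx, , drop = FALSE])
  out <- lapply(out, function(d) { rownames(d) <- NULL; d })
  attr(out$train, "spec") <- spec
  attr(out$test, "spec") <- spec
  out
}

#' Read or write a cohort as CSV with a JSON sidecar
#'
#' The CSV has a header row `subject_id, age, sex, site, diagnosis` followed
#' by one column per ROI; the sidecar `<path>.spec.json` stores the
#' [cohort_spec()] (including the seed) for provenance.
#'
#' @param table cohort data frame.
#' @param path CSV file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` the
#'   cohort data frame with the spec re-attached when the sidecar exists.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  spec <- attr(table, "spec")
  if (!is.null(spec)) {
    side <- unclass(spec)
    side$true_weights <- NULL
    jsonlite::write_json(side, paste0(path, ".spec.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  side <- paste0(path, ".spec.json")
  if (file.exists(side)) {
    js <- jsonlite::read_json(side, simplifyVector = TRUE)
    sp <- try(cohort_spec(
      n_hc = js$n_hc, n_ad = js$n_ad, age_min = js$age_min,
      age_max = js$age_max, sex_fraction_female = js$sex_fraction_female,
      sites = unlist(js$sites), n_rois = js$n_rois, roi_names = js$roi_names,
      noise_precision_true = js$noise_precision_true,
      warp_true = unlist(js$warp_true), ad_effect = unlist(js$ad_effect),
      mtl_rois = js$mtl_rois, age_density = js$age_density,
      ad_age_bias = js$ad_age_bias, warp_offset = js$warp_offset,
      seed = js$seed), silent = TRUE)
    if (!inherits(sp, "try-error")) attr(tab, "spec") <- sp
  }
  tab
}
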