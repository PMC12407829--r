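#' Basis specification for normative models
#'
#' Describes the fixed-effect design used by [wblr()]: an intercept, a cubic
#' B-spline expansion of (standardized) age with evenly spaced interior knots,
#' a binary sex column and dummy-coded site columns (reference site omitted).
#' Knot locations, the age standardizer and the site/sex level sets are frozen
#' on the training data by [basis_prepare()] and reused at prediction time.
#'
#' @param spline_degree spline degree; 3 (cubic) is the default and the only
#'   degree exercised by the benchmark.
#' @param n_interior_knots number of interior knots, evenly spaced over the
#'   training age range.
#' @param spline_sex if `TRUE`, the age spline is interacted with sex instead
#'   of entering sex as a single binary column. Off by default: a spline on a
#'   binary covariate is degenerate, so sex is modeled as an additive shift.
#' @return an object of class `nb_basis`.
#' @export
basis_spec <- function(spline_degree = 3L, n_interior_knots = 3L,
                       spline_sex = FALSE) {
  stopifnot(spline_degree >= 1L, n_interior_knots >= 1L)
  structure(
    list(spline_degree = as.integer(spline_degree),
         n_interior_knots = as.integer(n_interior_knots),
         spline_sex = isTRUE(spline_sex),
         prepared = FALSE),
    class = "nb_basis")
}

#' Freeze a basis on training data
#'
#' Computes the age standardizer, knot sequence and the known sex/site levels
#' from a training cohort. Interior knots are evenly spaced over the training
#' age range with clamped (repeated) boundary knots; ages outside the span are
#' handled at evaluation time by linear extension of the basis.
#'
#' @param basis an [basis_spec()] object.
#' @param data a cohort data frame with columns `age`, `sex`, `site`.
#' @return the basis with knots and level sets attached (`prepared = TRUE`).
#' @export
basis_prepare <- function(basis, data) {
  stopifnot(inherits(basis, "nb_basis"))
  check_cohort_columns(data)
  age <- data$age
  if (anyNA(age)) stop("missing ages in training data", call. = FALSE)
  ctr <- mean(age); scl <- stats::sd(age)
  if (!is.finite(scl) || scl <= 0) scl <- 1
  x <- (age - ctr) / scl
  lo <- min(x); hi <- max(x)
  if (hi <= lo) { lo <- lo - 0.5; hi <- hi + 0.5 }  # degenerate single-age pool
  interior <- seq(lo, hi, length.out = basis$n_interior_knots + 2L)
  interior <- interior[-c(1L, length(interior))]
  ord <- basis$spline_degree + 1L
  basis$age_center <- ctr
  basis$age_scale <- scl
  basis$knots <- c(rep(lo, ord), interior, rep(hi, ord))
  basis$span <- c(lo, hi)
  basis$site_levels <- sort(unique(as.character(data$site)))
  basis$sex_levels <- c("F", "M")
  basis$prepared <- TRUE
  basis
}

# Evaluate the clamped B-spline basis at standardized ages, with linear
# extension beyond the training span (value + slope at the nearest edge).
spline_columns <- function(x, basis) {
  ord <- basis$spline_degree + 1L
  lo <- basis$span[1]; hi <- basis$span[2]
  xc <- pmin(pmax(x, lo), hi)
  B <- splines::splineDesign(basis$knots, xc, ord = ord)
  out <- which(x < lo | x > hi)
  if (length(out)) {
    D1 <- splines::splineDesign(basis$knots, xc[out], ord = ord,
                                derivs = rep(1L, length(out)))
    B[out, ] <- B[out, , drop = FALSE] + D1 * (x[out] - xc[out])
  }
  # drop the first column: with an explicit intercept the full basis is
  # collinear (partition of unity)
  B[, -1L, drop = FALSE]
}

#' Build the design matrix for a cohort
#'
#' Rows align with subjects; columns are intercept, B-spline(age), sex
#' (M = 1) and site dummies (first site in sorted order is the reference).
#'
#' @param data cohort data frame with `age`, `sex`, `site` columns.
#' @param basis a prepared basis (see [basis_prepare()]); an unprepared spec
#'   is prepared on `data` itself.
#' @param unseen_site what to do with site labels unknown to the basis:
#'   `"error"` (default) or `"zero"` (all site dummies zero; used by transfer
#'   adaptation where reference and target sites are disjoint).
#' @return numeric matrix with one row per subject.
#' @export
build_design <- function(data, basis, unseen_site = c("error", "zero")) {
  unseen_site <- match.arg(unseen_site)
  stopifnot(inherits(basis, "nb_basis"))
  if (!isTRUE(basis$prepared)) basis <- basis_prepare(basis, data)
  check_cohort_columns(data)
  x <- (data$age - basis$age_center) / basis$age_scale
  S <- spline_columns(x, basis)
  colnames(S) <- paste0("bspl", seq_len(ncol(S)))
  sex <- as.character(data$sex)
  bad_sex <- setdiff(unique(sex), basis$sex_levels)
  if (length(bad_sex))
    stop("unknown sex label(s): ", paste(bad_sex, collapse = ", "), call. = FALSE)
  sexM <- as.numeric(sex == "M")
  site <- as.character(data$site)
  unknown <- setdiff(unique(site), basis$site_levels)
  if (length(unknown) && unseen_site == "error")
    stop("site label(s) not seen at training time: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  dummy_levels <- basis$site_levels[-1L]
  D <- matrix(0, nrow(data), length(dummy_levels),
              dimnames = list(NULL, if (length(dummy_levels))
                paste0("site", dummy_levels) else NULL))
  for (lv in dummy_levels) D[site == lv, paste0("site", lv)] <- 1
  use_sex <- basis$use_sex %||% TRUE
  if (!use_sex) {
    Phi <- cbind(`(Intercept)` = 1, S, D)
  } else if (basis$spline_sex) {
    Phi <- cbind(`(Intercept)` = 1, S, S * sexM, sexM = sexM, D)
    colnames(Phi)[seq_len(ncol(S)) + 1L + ncol(S)] <-
      paste0(colnames(S), ":sexM")
  } else {
    Phi <- cbind(`(Intercept)` = 1, S, sexM = sexM, D)
  }
  Phi
}

check_cohort_columns <- function(data) {
  need <- c("age", "sex", "site")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("cohort data must have columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}
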