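#' Linear mixed model for model-fit metrics
#'
#' Fits `outcome ~ log(n) x strategy + (1 | roi)` by REML on a long benchmark
#' table. The outcome and `log(n)` (natural log) are z-standardized before
#' fitting so coefficients are comparable across metrics; the representative
#' strategy is the reference level. p-values are Wald (normal approximation
#' on estimate / SE).
#'
#' @param rows data frame with columns `roi`, `strategy`, `n`, `iteration`
#'   and the outcome column.
#' @param outcome name of the outcome column (e.g. `"msll"`).
#' @return object of class `nb_lmm`: list with `coefficients` (term, beta,
#'   se, p), `ranef_variance`, `n_obs`, `converged`, `formula_id` and the
#'   standardization constants.
#' @export
fit_lmm_fit_metrics <- function(rows, outcome) {
  rows <- as.data.frame(rows)
  check_lmm_input(rows, outcome, c("roi", "strategy", "n"))
  if (length(unique(rows$roi)) < 2)
    stop("need >= 2 ROIs for a ROI random intercept", call. = FALSE)
  d <- standardize_lmm(rows, outcome)
  multi <- nlevels(d$data$strategy) > 1
  fml <- if (multi) y_std ~ logn_std * strategy + (1 | roi)
         else y_std ~ logn_std + (1 | roi)
  fit_nb_lmm(fml, d, "fit_metrics", outcome)
}

#' Linear mixed model for deviation-score outcomes
#'
#' Fits `outcome ~ log(n) x strategy x group + (1 | subject_id)` (references:
#' representative strategy, HC group) on per-subject benchmark outcomes such
#' as z-score MSE or total outlier counts. Age and sex are deliberately not
#' included as subject-level covariates. Standardization and p-values as in
#' [fit_lmm_fit_metrics()].
#'
#' @param rows data frame with `subject_id`, `group`, `strategy`, `n`,
#'   `iteration` and the outcome column.
#' @inheritParams fit_lmm_fit_metrics
#' @return an `nb_lmm` object.
#' @export
fit_lmm_deviation <- function(rows, outcome) {
  rows <- as.data.frame(rows)
  check_lmm_input(rows, outcome, c("subject_id", "group", "strategy", "n"))
  if (length(unique(rows$subject_id)) < 2)
    stop("single individual; random intercept unidentifiable", call. = FALSE)
  if (length(unique(rows$group)) < 2)
    stop("both groups (HC, AD) must be present", call. = FALSE)
  d <- standardize_lmm(rows, outcome)
  d$data$group <- stats::relevel(factor(d$data$group), ref = "HC")
  multi <- nlevels(d$data$strategy) > 1
  fml <- if (multi) y_std ~ logn_std * strategy * group + (1 | subject_id)
         else y_std ~ logn_std * group + (1 | subject_id)
  fit_nb_lmm(fml, d, "deviation", outcome)
}

#' Per-ROI fixed-effect models with FDR correction
#'
#' Fits one fixed-effects linear model per ROI (`outcome ~ log(n) x
#' strategy`, standardized as in [fit_lmm_fit_metrics()]) and applies
#' Benjamini-Hochberg adjustment across ROIs within each term.
#'
#' @inheritParams fit_lmm_fit_metrics
#' @return data frame `roi`, `term`, `beta`, `p`, `p_adj`.
#' @export
per_roi_lmm_fdr <- function(rows, outcome) {
  rows <- as.data.frame(rows)
  check_lmm_input(rows, outcome, c("roi", "strategy", "n"))
  rois <- unique(rows$roi)
  if (length(rois) < 2) stop("need >= 2 ROIs", call. = FALSE)
  res <- do.call(rbind, lapply(rois, function(r) {
    d <- standardize_lmm(rows[rows$roi == r, , drop = FALSE], outcome)
    multi <- nlevels(d$data$strategy) > 1
    fml <- if (multi) y_std ~ logn_std * strategy else y_std ~ logn_std
    fit <- stats::lm(fml, data = d$data)
    sm <- summary(fit)$coefficients
    data.frame(roi = r, term = rownames(sm), beta = sm[, 1], p = sm[, 4])
  }))
  rownames(res) <- NULL
  res$p_adj <- NA_real_
  for (t in unique(res$term)) {
    sel <- res$term == t
    res$p_adj[sel] <- stats::p.adjust(res$p[sel], method = "BH")
  }
  res
}

check_lmm_input <- function(rows, outcome, need) {
  miss <- setdiff(c(need, outcome), names(rows))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(rows[c(intersect(c("roi", "subject_id"), names(rows)),
                           "strategy", "n",
                           intersect("iteration", names(rows)))]))
    warning("duplicated design rows; estimates unchanged, n_obs inflated")
  invisible(TRUE)
}

standardize_lmm <- function(rows, outcome) {
  y <- rows[[outcome]]
  ln <- log(rows$n)
  m_y <- mean(y); s_y <- stats::sd(y)
  m_l <- mean(ln); s_l <- stats::sd(ln)
  if (!is.finite(s_y) || s_y == 0) s_y <- 1
  if (!is.finite(s_l) || s_l == 0) s_l <- 1
  d <- rows
  d$y_std <- (y - m_y) / s_y
  d$logn_std <- (ln - m_l) / s_l
  strat <- factor(d$strategy)
  if ("representative" %in% levels(strat))
    strat <- stats::relevel(strat, ref = "representative")
  d$strategy <- strat
  list(data = d, m_y = m_y, s_y = s_y, m_logn = m_l, s_logn = s_l)
}

fit_nb_lmm <- function(fml, d, formula_id, outcome) {
  converged <- TRUE
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = d$data, REML = TRUE),
    warning = function(w) {
      if (grepl("converge|singular", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  if (length(fit@optinfo$conv$lme4$messages %||% character(0)))
    converged <- FALSE
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  p <- 2 * stats::pnorm(-abs(beta / se))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    outcome = outcome, formula_id = formula_id,
    coefficients = data.frame(term = names(beta), beta = unname(beta),
                              se = unname(se), p = unname(p)),
    ranef_variance = stats::setNames(vc$vcov, vc$grp),
    n_obs = nrow(d$data), converged = converged,
    standardization = d[c("m_y", "s_y", "m_logn", "s_logn")],
    fit = fit),
    class = "nb_lmm")
}

#' @export
print.nb_lmm <- function(x, ...) {
  cat(sprintf("Linear mixed model (%s), outcome = %s, n_obs = %d%s\n",
              x$formula_id, x$outcome, x$n_obs,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  co <- x$coefficients
  co$beta <- sprintf("% .3f", co$beta)
  co$p <- format.pval(co$p, digits = 3, eps = 1e-3)
  print(co, row.names = FALSE)
  invisible(x)
}

#' Map standardized LMM coefficients back to the raw scale
#'
#' Inverts the outcome and log(n) standardization of an `nb_lmm`, returning
#' coefficients of the equivalent model fitted on the unstandardized outcome
#' against unstandardized `log(n)` (factor codings unchanged).
#'
#' @param x an `nb_lmm` object.
#' @return named numeric vector of raw-scale fixed effects.
#' @export
lmm_destandardize <- function(x) {
  st <- x$standardization
  co <- stats::setNames(x$coefficients$beta, x$coefficients$term)
  raw <- stats::setNames(rep(0, length(co)), names(co))
  for (t in names(co)) {
    parts <- strsplit(t, ":", fixed = TRUE)[[1]]
    has_ln <- "logn_std" %in% parts
    if (has_ln) {
      raw[t] <- raw[t] + st$s_y * co[t] / st$s_logn
      other <- paste(setdiff(parts, "logn_std"), collapse = ":")
      if (other == "") other <- "(Intercept)"
      raw[other] <- raw[other] - st$s_y * co[t] * st$m_logn / st$s_logn
    } else {
      raw[t] <- raw[t] + st$s_y * co[t]
    }
  }
  raw["(Intercept)"] <- raw["(Intercept)"] + st$m_y
  names(raw) <- sub("logn_std", "logn", names(raw))
  raw
}
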