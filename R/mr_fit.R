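#' Per-SNV Wald ratios
#'
#' First stage of every ratio-based estimator: `ratio_j = by_j / bx_j`
#' with first-order standard error `sy_j / |bx_j|` (the default), or the
#' second-order expansion that also propagates the exposure SE.
#' SNVs with a zero exposure beta are excluded with a warning.
#'
#' @param h a [harmonize()]d set.
#' @param exposure column index or trait name of the exposure.
#' @param se_method `"first"` (default) or `"second"` order delta-method
#'   SE.
#' @return object of class `ratio_set`: data frame with `rsid`, `ratio`,
#'   `se`, `weight` (`1/se^2`).
#' @export
wald_ratios <- function(h, exposure = 1L, se_method = c("first", "second")) {
  se_method <- match.arg(se_method)
  k <- if (is.character(exposure)) match(exposure, h$exposure_traits) else
    as.integer(exposure)
  if (is.na(k) || k < 1L || k > ncol(h$bx)) stop("unknown exposure: ", exposure)
  bx <- h$bx[, k]; sx <- h$sx[, k]
  zero <- bx == 0
  if (any(zero)) {
    warning("excluding SNV(s) with zero exposure beta: ",
            paste(h$rsids[zero], collapse = ", "))
  }
  i <- which(!zero)
  ratio <- h$by[i] / bx[i]
  se <- switch(se_method,
    first = h$sy[i] / abs(bx[i]),
    second = sqrt(h$sy[i]^2 / bx[i]^2 + h$by[i]^2 * sx[i]^2 / bx[i]^4))
  structure(data.frame(rsid = h$rsids[i], ratio = ratio, se = se,
                       weight = 1 / se^2, stringsAsFactors = FALSE,
                       row.names = NULL),
            exposure = h$exposure_traits[k], outcome = h$outcome_trait,
            class = c("ratio_set", "data.frame"))
}

.mr_estimate <- function(method, beta, se, n_snv, exposure, outcome,
                         extra = list()) {
  z <- beta / se
  est <- c(list(method = method, exposure = exposure, outcome = outcome,
                beta = beta, se = se,
                ci_low = beta - qnorm(0.975) * se,
                ci_high = beta + qnorm(0.975) * se,
                odds_ratio = exp(beta),
                or_ci_low = exp(beta - qnorm(0.975) * se),
                or_ci_high = exp(beta + qnorm(0.975) * se),
                pval = 2 * pnorm(-abs(z)),
                n_snv = n_snv),
           extra)
  structure(est, class = "mr_fit")
}

#' Fit a univariable two-sample MR estimator
#'
#' Estimates the causal effect (log-odds of outcome per SD of exposure)
#' from a harmonized instrument set, by one of:
#' \describe{
#'   \item{`ivw_mre`}{multiplicative random-effect inverse-variance
#'     weighted mean of the Wald ratios; the point estimate equals the
#'     fixed-effect one, the SE is inflated by
#'     `max(1, sqrt(Q / (J - 1)))`.}
#'   \item{`ivw_fe`}{fixed-effect IVW, SE `(sum w_j)^{-1/2}`.}
#'   \item{`simple_median`}{median of the Wald ratios; bootstrap SE.}
#'   \item{`weighted_median`}{50th percentile of the inverse-variance
#'     weighted CDF over the sorted ratios with linear interpolation;
#'     bootstrap SE.}
#'   \item{`penalized_median`}{weighted median with weights
#'     down-weighted by `min(1, penalty * p_j)` where `p_j` is the
#'     upper-tail chi-square(1) p-value of the SNV's heterogeneity
#'     contribution about the weighted-median estimate.}
#'   \item{`egger`}{weighted regression of outcome on exposure betas with
#'     a free intercept (instruments re-oriented so all exposure betas
#'     are positive); the intercept and its p-value index directional
#'     pleiotropy.}
#' }
#' Confidence intervals use the normal 1.96 multiplier and p-values the
#' normal reference throughout; the odds ratio is `exp(beta)` with an
#' exponentiated CI.
#'
#' @param h a [harmonize()]d set (or, for ratio-based methods, a
#'   precomputed [wald_ratios()] `ratio_set`).
#' @param exposure exposure column index or trait name.
#' @param method estimator, see above.
#' @param boot_reps parametric bootstrap replicates for median SEs
#'   (default 1000).
#' @param seed seed for the bootstrap (default 1).
#' @param penalty penalization constant for the penalized weighted
#'   median (default 20).
#' @param se_method Wald-ratio SE order, see [wald_ratios()].
#' @return object of class `mr_fit` with elements `method`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `odds_ratio` (+ CI), `pval`, `n_snv`, and for
#'   Egger also `egger_intercept`, `intercept_se`, `intercept_pval`.
#' @export
mr_fit <- function(h, exposure = 1L,
                   method = c("ivw_mre", "ivw_fe", "simple_median",
                              "weighted_median", "penalized_median",
                              "egger"),
                   boot_reps = 1000L, seed = 1L, penalty = 20,
                   se_method = c("first", "second")) {
  method <- match.arg(method)
  if (method == "egger") {
    if (!inherits(h, "harmonized_set"))
      stop("egger requires a harmonized_set (needs exposure betas)")
    return(.egger_fit(h, exposure))
  }
  r <- if (inherits(h, "ratio_set")) h else
    wald_ratios(h, exposure, match.arg(se_method))
  switch(method,
    ivw_mre = .ivw(r, "multiplicative_random"),
    ivw_fe = .ivw(r, "fixed"),
    simple_median = .median_fit(r, "simple", boot_reps, seed),
    weighted_median = .median_fit(r, "weighted", boot_reps, seed),
    penalized_median = .median_fit(r, "penalized", boot_reps, seed, penalty))
}

.ivw <- function(r, mode = c("multiplicative_random", "fixed")) {
  mode <- match.arg(mode)
  J <- nrow(r)
  if (J == 0L) stop("no instruments left for IVW")
  w <- r$weight
  beta <- sum(w * r$ratio) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  if (J == 1L)
    return(.mr_estimate("ivw_fe", beta, se_fixed, 1L,
                        attr(r, "exposure"), attr(r, "outcome")))
  q <- sum(w * (r$ratio - beta)^2)
  if (mode == "fixed") {
    .mr_estimate("ivw_fe", beta, se_fixed, J,
                 attr(r, "exposure"), attr(r, "outcome"),
                 list(q_stat = q, q_df = J - 1L))
  } else {
    se <- se_fixed * max(1, sqrt(q / (J - 1)))
    .mr_estimate("ivw_mre", beta, se, J,
                 attr(r, "exposure"), attr(r, "outcome"),
                 list(q_stat = q, q_df = J - 1L))
  }
}

# Weighted median: 50th percentile of the weight-standardized CDF over
# sorted ratios, linear interpolation between the midpoints
# p_i = (S_i - w_i/2) / S_J of the cumulative weights.
.weighted_median <- function(ratio, weight) {
  o <- order(ratio)
  b <- ratio[o]; w <- weight[o]
  p <- (cumsum(w) - 0.5 * w) / sum(w)
  if (p[1] >= 0.5) return(b[1])
  if (p[length(p)] <= 0.5) return(b[length(b)])
  i <- max(which(p < 0.5))
  b[i] + (b[i + 1] - b[i]) * (0.5 - p[i]) / (p[i + 1] - p[i])
}

.penalized_weights <- function(ratio, weight, penalty) {
  center <- .weighted_median(ratio, weight)
  qj <- weight * (ratio - center)^2
  pj <- pchisq(qj, df = 1, lower.tail = FALSE)
  weight * pmin(1, penalty * pj)
}

.median_fit <- function(r, variant, boot_reps, seed, penalty = 20) {
  J <- nrow(r)
  if (J < 3L) stop("median estimators need at least 3 instruments")
  point <- function(ratio) {
    switch(variant,
      simple = .weighted_median(ratio, rep(1, length(ratio))),
      weighted = .weighted_median(ratio, r$weight),
      penalized = .weighted_median(ratio,
                                   .penalized_weights(ratio, r$weight,
                                                      penalty)))
  }
  beta <- point(r$ratio)
  boots <- withr_seed(seed, {
    vapply(seq_len(boot_reps), function(i)
      point(rnorm(J, mean = r$ratio, sd = r$se)), numeric(1))
  })
  se <- sd(boots)
  .mr_estimate(paste0(variant, "_median"), beta, se, J,
               attr(r, "exposure"), attr(r, "outcome"))
}

# Evaluate expr under a local RNG state so callers' streams are untouched.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.egger_fit <- function(h, exposure = 1L) {
  k <- if (is.character(exposure)) match(exposure, h$exposure_traits) else
    as.integer(exposure)
  bx <- h$bx[, k]; by <- h$by; sy <- h$sy
  ok <- bx != 0
  bx <- bx[ok]; by <- by[ok]; sy <- sy[ok]
  J <- length(bx)
  if (J < 3L) stop("MR-Egger needs at least 3 instruments")
  # Egger is not invariant to allele orientation: re-code so bx > 0.
  flip <- sign(bx)
  bx <- bx * flip; by <- by * flip
  if (diff(range(bx)) < .Machine$double.eps^0.5)
    stop("exposure betas are collinear after orientation")
  fit <- lm(by ~ bx, weights = 1 / sy^2)
  sm <- summary(fit)
  # multiplicative residual scale floored at 1: SEs cannot undershoot the
  # fixed-effect (sigma = 1) model
  scale <- max(1, sm$sigma) / sm$sigma
  slope <- coef(fit)[["bx"]]
  slope_se <- sm$coefficients["bx", "Std. Error"] * scale
  int <- coef(fit)[["(Intercept)"]]
  int_se <- sm$coefficients["(Intercept)", "Std. Error"] * scale
  .mr_estimate("egger", slope, slope_se, J,
               h$exposure_traits[k], h$outcome_trait,
               list(egger_intercept = int, intercept_se = int_se,
                    intercept_pval = 2 * pnorm(-abs(int / int_se)),
                    q_stat = sum((by - fitted(fit))^2 / sy^2),
                    q_df = J - 2L))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (ratio_j - center)^2` over the per-SNV Wald ratios, with
#' `J - 1` degrees of freedom about the IVW centre (or `J - 2` about an
#' Egger fit); the p-value is the upper chi-square tail.
#'
#' @param r a [wald_ratios()] `ratio_set`.
#' @param center the causal estimate the deviations are measured about
#'   (default the fixed-effect IVW estimate).
#' @param df_drop 1 for IVW (default), 2 for Egger.
#' @return list with `q_stat`, `df`, `pval`.
#' @export
cochran_q <- function(r, center = NULL, df_drop = 1L) {
  J <- nrow(r)
  if (J < 2L) stop("Cochran's Q needs at least 2 instruments")
  if (is.null(center)) center <- sum(r$weight * r$ratio) / sum(r$weight)
  q <- sum(r$weight * (r$ratio - center)^2)
  df <- J - df_drop
  list(q_stat = q, df = df, pval = pchisq(q, df, lower.tail = FALSE))
}

#' Bonferroni threshold for the exposure-outcome grid
#'
#' `alpha / (n_exposures * n_outcomes)`; with 4 iron biomarkers and 3
#' kidney-disease outcomes at `alpha = 0.05` this is 0.05/12 ~= 0.0042.
#'
#' @param n_exposures number of exposures tested.
#' @param n_outcomes number of outcomes tested.
#' @param alpha family-wise error rate (default 0.05).
#' @return the per-test threshold.
#' @export
bonferroni_threshold <- function(n_exposures, n_outcomes, alpha = 0.05) {
  stopifnot(n_exposures >= 1, n_outcomes >= 1)
  alpha / (n_exposures * n_outcomes)
}

#' Classify a p-value against the Bonferroni and nominal levels
#'
#' `"significant"` below the Bonferroni threshold, `"suggestive"` between
#' the threshold and `alpha`, `"null"` otherwise.
#'
#' @param pval p-value(s).
#' @param threshold Bonferroni threshold (see [bonferroni_threshold()]).
#' @param alpha nominal level (default 0.05); must be `>= threshold`.
#' @return character vector of labels.
#' @export
classify_significance <- function(pval, threshold, alpha = 0.05) {
  stopifnot(threshold <= alpha)
  ifelse(pval < threshold, "significant",
         ifelse(pval < alpha, "suggestive", "null"))
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("MR estimate (%s): %s -> %s, %d SNVs\n", x$method,
              x$exposure, x$outcome, x$n_snv))
  cat(sprintf("  beta = %.*f (SE %.*f), OR = %.*f [%.*f, %.*f], p = %.3g\n",
              digits, x$beta, digits, x$se, digits, x$odds_ratio,
              digits, x$or_ci_low, digits, x$or_ci_high, x$pval))
  if (!is.null(x$egger_intercept))
    cat(sprintf("  intercept = %.*f (p = %.3g)\n", digits,
                x$egger_intercept, x$intercept_pval))
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  out <- c(beta = object$beta)
  if (!is.null(object$egger_intercept))
    out <- c(intercept = object$egger_intercept, out)
  out
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  m <- rbind(beta = c(object$beta - z * object$se,
                      object$beta + z * object$se))
  if (!is.null(object$egger_intercept))
    m <- rbind(m, intercept = c(object$egger_intercept -
                                  z * object$intercept_se,
                                object$egger_intercept +
                                  z * object$intercept_se))
  colnames(m) <- sprintf("%g %%", 100 * c((1 - level) / 2,
                                          1 - (1 - level) / 2))
  m
}

#' @export
summary.mr_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Run every univariable estimator for every exposure
#'
#' Convenience wrapper producing the tidy per-method results table (the
#' machine-readable twin of a forest plot): one row per exposure and
#' method, with estimate, OR, CI, p-value and Egger intercept columns.
#'
#' @param h a [harmonize()]d set.
#' @param methods estimators to run (default all six).
#' @param boot_reps,seed,penalty see [mr_fit()].
#' @return data frame with columns `exposure`, `outcome`, `method`,
#'   `n_snv`, `beta`, `se`, `or`, `ci_low`, `ci_high`, `pval`,
#'   `egger_intercept`, `intercept_pval`.
#' @export
mr_all_methods <- function(h, methods = c("ivw_mre", "ivw_fe",
                                          "simple_median",
                                          "weighted_median",
                                          "penalized_median", "egger"),
                           boot_reps = 1000L, seed = 1L, penalty = 20) {
  rows <- list()
  for (k in seq_along(h$exposure_traits)) {
    for (m in methods) {
      fit <- mr_fit(h, k, method = m, boot_reps = boot_reps, seed = seed,
                    penalty = penalty)
      rows[[length(rows) + 1L]] <- data.frame(
        exposure = fit$exposure, outcome = fit$outcome, method = fit$method,
        n_snv = fit$n_snv, beta = fit$beta, se = fit$se,
        or = fit$odds_ratio, ci_low = fit$or_ci_low,
        ci_high = fit$or_ci_high, pval = fit$pval,
        egger_intercept = fit$egger_intercept %||% NA_real_,
        intercept_pval = fit$intercept_pval %||% NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
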