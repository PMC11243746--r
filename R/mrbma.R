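# Weighted design for MR-BMA: precision-scale response and columns
# standardized to unit weighted norm (scale factors kept for
# back-transforming coefficients).
.bma_design <- function(h) {
  y <- h$by / h$sy
  X <- h$bx / h$sy
  cs <- sqrt(colSums(X^2))
  if (any(cs == 0)) stop("exposure column with all-zero effects")
  list(y = y, X = sweep(X, 2, cs, "/"), col_scale = cs)
}

# Closed-form Gaussian marginal log-likelihood of y ~ N(0, I + v X X')
# and the posterior mean of the (standardized) coefficients, via the
# p x p inner matrix.
.bma_model_fit <- function(y, X, prior_sd) {
  J <- length(y)
  if (is.null(X) || ncol(X) == 0L) {
    return(list(mloglik = sum(dnorm(y, 0, 1, log = TRUE)),
                theta = numeric(0)))
  }
  v <- prior_sd^2
  A <- crossprod(X) + diag(1 / v, ncol(X))   # X'X + I/v
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(list(mloglik = -Inf, theta = rep(NA_real_,
                                                           ncol(X))))
  Xty <- crossprod(X, y)
  theta <- backsolve(ch, forwardsolve(t(ch), Xty))
  # log|I + v X X'| = log|A| + p log v ; quad form via Woodbury
  logdet <- 2 * sum(log(diag(ch))) + ncol(X) * log(v)
  quad <- sum(y^2) - sum(Xty * theta)
  list(mloglik = -0.5 * (J * log(2 * pi) + logdet + quad),
       theta = drop(theta))
}

#' Multivariable MR by Bayesian model averaging
#'
#' Enumerates all subsets of the exposure biomarkers (including the empty
#' model) and scores each by the closed-form Gaussian marginal likelihood
#' of the precision-weighted outcome effects regressed on the member
#' exposure-effect columns, under a zero-centred normal shrinkage prior
#' of SD `prior_sd` on the standardized coefficients (columns scaled to
#' unit weighted norm) and an independent inclusion prior `prior_incl`
#' per factor.  Reports per-model posterior probabilities (PP), each
#' factor's marginal inclusion probability (MIP, the summed PP of the
#' models containing it) and model-averaged causal estimate
#' (`theta_mace`), with per-model conditional estimates back-transformed
#' to the per-SD exposure scale.
#'
#' When `remove_outliers` is `TRUE`, per-instrument diagnostics
#' ([iv_diagnostics()]) are computed on the highest-PP non-empty model;
#' instruments with a heterogeneity contribution `Q > q_cut` or Cook's
#' distance above the median of the corresponding F distribution are
#' removed and the model space refitted once.
#'
#' @param h a [harmonize()]d set.
#' @param prior_incl prior inclusion probability per factor
#'   (default 0.5).
#' @param prior_sd prior SD of standardized causal effects
#'   (default 0.25).
#' @param remove_outliers apply the one-pass outlier rule
#'   (default TRUE).
#' @param q_cut heterogeneity-contribution removal threshold
#'   (default 10).
#' @return object of class `mr_bma`: list with `models` (data frame:
#'   `members`, `prior`, `marginal_loglik`, `pp`, `theta` as a
#'   comma-separated string), `mip`, `theta_mace` (named per factor),
#'   `diagnostics`, `removed`, `prior_incl`, `prior_sd`, `rsids`.
#' @export
mr_bma <- function(h, prior_incl = 0.5, prior_sd = 0.25,
                   remove_outliers = TRUE, q_cut = 10) {
  stopifnot(prior_incl >= 0, prior_incl <= 1, prior_sd > 0)
  fit1 <- .bma_posterior(h, prior_incl, prior_sd)
  diagnostics <- NULL
  removed <- character(0)
  if (remove_outliers) {
    nonempty <- fit1$models[fit1$models$members != "", , drop = FALSE]
    if (nrow(nonempty) > 0L && max(nonempty$pp) > 0) {
      best <- nonempty$members[which.max(nonempty$pp)]
      members <- match(strsplit(best, ",")[[1]], h$exposure_traits)
      diagnostics <- iv_diagnostics(h, members, q_cut = q_cut)
      removed <- diagnostics$rsid[diagnostics$removed]
      if (length(removed) > 0L && length(h$rsids) - length(removed) >
            length(members)) {
        h2 <- subset_harmonized(h, setdiff(h$rsids, removed))
        fit1 <- .bma_posterior(h2, prior_incl, prior_sd)
      }
    }
  }
  structure(c(fit1, list(diagnostics = diagnostics, removed = removed,
                         prior_incl = prior_incl, prior_sd = prior_sd)),
            class = "mr_bma")
}

.bma_posterior <- function(h, prior_incl, prior_sd) {
  K <- ncol(h$bx)
  d <- .bma_design(h)
  subsets <- lapply(0:(2^K - 1), function(m) which(bitwAnd(m, 2^(0:(K - 1)))
                                                   > 0))
  rows <- lapply(subsets, function(s) {
    f <- .bma_model_fit(d$y, if (length(s)) d$X[, s, drop = FALSE] else NULL,
                        prior_sd)
    theta <- if (length(s)) f$theta / d$col_scale[s] else numeric(0)
    log_prior <- if (prior_incl %in% c(0, 1)) {
      if ((prior_incl == 0 && length(s) > 0) ||
          (prior_incl == 1 && length(s) < K)) -Inf else 0
    } else {
      length(s) * log(prior_incl) + (K - length(s)) * log(1 - prior_incl)
    }
    list(members = s, theta = theta, mloglik = f$mloglik,
         log_post = log_prior + f$mloglik, log_prior = log_prior)
  })
  lp <- vapply(rows, `[[`, numeric(1), "log_post")
  lp[is.na(lp)] <- -Inf
  pp <- exp(lp - max(lp[is.finite(lp)]))
  pp[!is.finite(pp)] <- 0
  pp <- pp / sum(pp)
  mip <- setNames(numeric(K), h$exposure_traits)
  mace <- setNames(numeric(K), h$exposure_traits)
  for (i in seq_along(rows)) {
    s <- rows[[i]]$members
    if (length(s) > 0L && pp[i] > 0) {
      mip[s] <- mip[s] + pp[i]
      mace[s] <- mace[s] + pp[i] * rows[[i]]$theta
    }
  }
  models <- data.frame(
    members = vapply(rows, function(r)
      paste(h$exposure_traits[r$members], collapse = ","), character(1)),
    size = vapply(rows, function(r) length(r$members), integer(1)),
    prior = exp(vapply(rows, `[[`, numeric(1), "log_prior")),
    marginal_loglik = vapply(rows, `[[`, numeric(1), "mloglik"),
    pp = pp,
    theta = vapply(rows, function(r)
      paste(formatC(r$theta, digits = 6, format = "g"), collapse = ","),
      character(1)),
    stringsAsFactors = FALSE)
  models <- models[order(-models$pp), ]
  rownames(models) <- NULL
  list(models = models, mip = mip, theta_mace = mace, rsids = h$rsids,
       model_thetas = lapply(rows, function(r)
         setNames(r$theta, h$exposure_traits[r$members])))
}

#' Per-instrument diagnostics for a multivariable MR model
#'
#' From the precision-weighted least-squares fit of the outcome effects
#' on the member exposure columns: each instrument's heterogeneity
#' contribution `q_j = w_j (by_j - yhat_j)^2` and Cook's distance.  An
#' instrument is flagged for removal when `q_j > q_cut` or its Cook's
#' distance exceeds the median of the `F(p, J - p)` distribution
#' (`p` = number of member exposures).
#'
#' @param h a [harmonize()]d set.
#' @param members integer indices (or trait names) of the model's
#'   exposures.
#' @param q_cut heterogeneity threshold (default 10).
#' @return data frame with `rsid`, `q_contribution`, `cooks_distance`,
#'   `removed`, `rule`.
#' @export
iv_diagnostics <- function(h, members, q_cut = 10) {
  if (is.character(members)) members <- match(members, h$exposure_traits)
  stopifnot(length(members) >= 1L, !anyNA(members))
  J <- length(h$rsids)
  p <- length(members)
  if (J - p <= 0L) stop("diagnostics undefined: J - |model| <= 0")
  X <- h$bx[, members, drop = FALSE]
  dat <- data.frame(y = h$by, X)
  fit <- lm(y ~ . - 1, data = dat, weights = 1 / h$sy^2)
  q <- (h$by - fitted(fit))^2 / h$sy^2
  cd <- cooks.distance(fit)
  f_med <- qf(0.5, p, J - p)
  q_rule <- q > q_cut
  cd_rule <- cd > f_med
  rule <- ifelse(q_rule & cd_rule, "q+cd",
                 ifelse(q_rule, "q", ifelse(cd_rule, "cd", "")))
  data.frame(rsid = h$rsids, q_contribution = unname(q),
             cooks_distance = unname(cd), removed = q_rule | cd_rule,
             rule = rule, stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.mr_bma <- function(x, ...) {
  cat(sprintf("Multivariable MR (Bayesian model averaging), %d SNVs\n",
              length(x$rsids)))
  cat(sprintf("  priors: inclusion %.2f, effect SD %.2f\n",
              x$prior_incl, x$prior_sd))
  rank <- order(-x$mip)
  cat("  factor ranking (MIP, theta_MACE):\n")
  for (k in rank)
    cat(sprintf("    %-10s %.3f  %+.3f\n", names(x$mip)[k], x$mip[k],
                x$theta_mace[k]))
  if (length(x$removed) > 0L)
    cat("  instruments removed as outliers:",
        paste(x$removed, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mr_bma <- function(object, top = 10L, ...) {
  print(object)
  cat("  best individual models (non-empty), by PP:\n")
  m <- object$models[object$models$members != "", , drop = FALSE]
  print(utils::head(m[, c("members", "pp", "theta")], top))
  invisible(object)
}
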