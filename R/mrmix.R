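#' EM fit of a two-component zero-mean normal mixture
#'
#' Models residuals `r_j` as a mixture of a "valid" component
#' `N(0, base_var_j)` (mixing weight `pi0`) and an "invalid" component
#' `N(0, base_var_j + sigma2)`.  `pi0` has a closed-form M-step; `sigma2`
#' is updated by a one-dimensional search (generalized EM, since the
#' per-observation base variances leave no closed form), so the observed
#' log-likelihood is non-decreasing across iterations.
#'
#' @param residuals numeric vector.
#' @param base_var per-observation valid-component variances (> 0).
#' @param init numeric `c(pi0, sigma2)` initial values; default
#'   `pi0 = 0.5`, `sigma2 = var(residuals) / 2`.
#' @param max_iter iteration cap (default 10000).
#' @param tol stop when the log-likelihood gain drops below this
#'   (default 1e-8).
#' @return list with `pi0`, `sigma2`, `loglik`, `iters`, `converged`, and
#'   `loglik_trace` (per-iteration log-likelihoods).
#' @export
em_mixture <- function(residuals, base_var,
                       init = c(0.5, max(var(residuals) / 2, 1e-10)),
                       max_iter = 10000L, tol = 1e-8) {
  stopifnot(length(residuals) == length(base_var), all(base_var > 0))
  pi0 <- min(max(init[1], 1e-6), 1 - 1e-6)
  sigma2 <- max(init[2], 0)
  sigma2_hi <- max(10 * var(c(residuals, 0)), 10 * max(base_var), sigma2, 1)
  loglik <- function(pi0, sigma2) {
    sum(log(pi0 * dnorm(residuals, 0, sqrt(base_var)) +
            (1 - pi0) * dnorm(residuals, 0, sqrt(base_var + sigma2))))
  }
  ll <- loglik(pi0, sigma2)
  trace <- ll
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    d_valid <- pi0 * dnorm(residuals, 0, sqrt(base_var))
    d_invalid <- (1 - pi0) * dnorm(residuals, 0, sqrt(base_var + sigma2))
    gamma <- d_valid / (d_valid + d_invalid)
    gamma[is.na(gamma)] <- 0.5
    pi0_new <- mean(gamma)
    # generalized M-step: maximize the invalid-component expected loglik
    obj <- function(s2) {
      -sum((1 - gamma) * dnorm(residuals, 0, sqrt(base_var + s2),
                               log = TRUE))
    }
    sigma2_new <- if (sum(1 - gamma) < 1e-12) sigma2 else {
      opt <- optimize(obj, c(0, sigma2_hi))
      if (obj(0) <= opt$objective) 0 else opt$minimum
    }
    ll_new <- loglik(pi0_new, sigma2_new)
    # guard: keep the previous parameters if the search step would
    # (numerically) decrease the likelihood
    if (ll_new < ll - 1e-12) {
      converged <- TRUE
      break
    }
    pi0 <- pi0_new; sigma2 <- sigma2_new
    trace <- c(trace, ll_new)
    if (ll_new - ll < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  list(pi0 = pi0, sigma2 = sigma2, loglik = ll, iters = iters,
       converged = converged, loglik_trace = trace)
}

# The mixture likelihood has a ridge when the data are homogeneous
# (sigma2 = 0 makes pi0 unidentifiable and EM stalls at its start), so
# the fit is run from several starts; among (near-)equal likelihoods the
# largest pi0 wins — the valid-dominated reading of a degenerate fit.
# An optional warm start (the neighbouring grid point's solution) speeds
# up the profile sweep.  A run that exhausts max_iter but whose final
# log-likelihood gain is below 1e-5 is accepted as converged.
.em_multistart <- function(residuals, base_var, max_iter, tol,
                           warm = NULL, light = FALSE) {
  v <- max(var(residuals) / 2, 1e-10)
  starts <- if (light && !is.null(warm)) list(c(0.999, 1e-8)) else
    list(c(0.999, 1e-8), c(0.5, v))
  if (!is.null(warm)) starts <- c(starts, list(warm))
  fits <- lapply(starts, function(s)
    em_mixture(residuals, base_var, init = s, max_iter = max_iter,
               tol = tol))
  # the degenerate all-valid fit (sigma2 = 0, pi0 at its ceiling) is a
  # candidate in its own right: EM walks off the likelihood ridge even
  # when the data carry no mixture signal
  ll_valid <- sum(dnorm(residuals, 0, sqrt(base_var), log = TRUE))
  fits <- c(fits, list(list(pi0 = 0.999, sigma2 = 0, loglik = ll_valid,
                            iters = 0L, converged = TRUE,
                            loglik_trace = ll_valid)))
  for (i in seq_along(fits)) {
    tr <- fits[[i]]$loglik_trace
    n <- length(tr)
    if (!fits[[i]]$converged && n >= 2L && tr[n] - tr[n - 1L] < 1e-5)
      fits[[i]]$converged <- TRUE
  }
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  pi0 <- vapply(fits, `[[`, numeric(1), "pi0")
  # Degeneracy guard: on clean data an interior optimum can beat the
  # sigma2 = 0 ridge by a small margin merely by fitting sampling
  # kurtosis with its two extra parameters.  A BIC-style margin of
  # log(J) decides when the mixture improvement is material; otherwise
  # the valid-dominated (largest-pi0) fit is preferred.
  near <- ll >= max(ll) - log(length(residuals))
  fits[near][[which.max(pi0[near])]]
}

# Rescale harmonized effects to the standardized (unit-variance trait,
# genotype-SD) scale the mixture model assumes.
.standardize_effects <- function(b, s, eaf, n, method = c("eaf", "zn")) {
  method <- match.arg(method)
  if (method == "eaf" && !anyNA(eaf)) {
    f <- sqrt(2 * eaf * (1 - eaf))
    list(b = b * f, s = s * f)
  } else {
    z <- b / s
    list(b = z / sqrt(n), s = 1 / sqrt(n))
  }
}

#' Mixture-model MR estimator
#'
#' Profiles the causal effect `theta` over a grid: at each grid value the
#' residuals `by_j - theta * bx_j` are fitted by [em_mixture()] with
#' valid-component variances `sy_j^2 + theta^2 sx_j^2`, and the returned
#' estimate is the grid value maximizing the fitted proportion of valid
#' instruments `pi0` (ties broken toward smaller `|theta|`).  A coarse
#' pass over `theta_range` is refined around its argmax at `fine_step`.
#' Robust to horizontal pleiotropy when a majority (or identifiable
#' mixture component) of instruments is valid.
#'
#' Effects are first rescaled to the standardized scale: by the
#' `2 f (1 - f)` allele-frequency factor when frequencies are available
#' (`standardize = "eaf"`), else by `z / sqrt(n)` (`"zn"`); `"none"`
#' uses the harmonized effects as given.
#'
#' @param h a [harmonize()]d set.
#' @param exposure exposure column index or trait name.
#' @param theta_range profiled interval (default `c(-0.5, 0.5)`).
#' @param coarse_step,fine_step grid steps of the two passes
#'   (defaults 0.01 and 0.001).
#' @param standardize `"eaf"`, `"zn"` or `"none"`.
#' @param max_iter,tol EM controls, see [em_mixture()].
#' @return object of class `mrmix`: list with `theta`, `pi0`, `sigma2`,
#'   `grid` (data frame of evaluated `theta`, `pi0`, `sigma2`, `loglik`,
#'   `converged`), `exposure`, `outcome`, `n_snv`.
#' @export
mrmix <- function(h, exposure = 1L, theta_range = c(-0.5, 0.5),
                  coarse_step = 0.01, fine_step = 0.001,
                  standardize = c("eaf", "zn", "none"),
                  max_iter = 10000L, tol = 1e-8) {
  standardize <- match.arg(standardize)
  k <- if (is.character(exposure)) match(exposure, h$exposure_traits) else
    as.integer(exposure)
  if (is.na(k)) stop("unknown exposure: ", exposure)
  bx <- h$bx[, k]; sx <- h$sx[, k]; by <- h$by; sy <- h$sy
  if (length(bx) < 4L) stop("mrmix needs at least 4 instruments")
  if (standardize != "none") {
    ex <- .standardize_effects(bx, sx, h$eaf, h$nx[, k], standardize)
    ou <- .standardize_effects(by, sy, h$eaf, h$ny, standardize)
    bx <- ex$b; sx <- ex$s; by <- ou$b; sy <- ou$s
  }
  eval_grid <- function(thetas, iter_cap = max_iter, light = FALSE) {
    warm <- NULL
    out <- vector("list", length(thetas))
    for (i in seq_along(thetas)) {
      th <- thetas[i]
      res <- by - th * bx
      bv <- sy^2 + th^2 * sx^2
      fit <- .em_multistart(res, bv, max_iter = iter_cap, tol = tol,
                            warm = warm, light = light)
      warm <- c(fit$pi0, fit$sigma2)
      out[[i]] <- data.frame(theta = th, pi0 = fit$pi0,
                             sigma2 = fit$sigma2, loglik = fit$loglik,
                             converged = fit$converged)
    }
    do.call(rbind, out)
  }
  # Grid values where the data look homogeneous form a pi0 plateau whose
  # fitted values differ only by EM noise; within the plateau
  # (pi0 within 1e-4 of the maximum) the profile log-likelihood — smooth
  # and maximized at the valid-model estimate — ranks candidates, and any
  # residual tie goes to the smaller |theta|.
  pick <- function(grid) {
    g <- grid[grid$converged, , drop = FALSE]
    if (nrow(g) == 0L) g <- grid
    best <- g[g$pi0 >= max(g$pi0) - 1e-4, , drop = FALSE]
    best <- best[best$loglik >= max(best$loglik) - 1e-7, , drop = FALSE]
    best[order(abs(best$theta), best$theta), ][1, , drop = FALSE]
  }
  coarse <- eval_grid(seq(theta_range[1], theta_range[2],
                          by = coarse_step),
                      iter_cap = min(max_iter, 200L), light = TRUE)
  c_best <- pick(coarse)
  lo <- max(theta_range[1], c_best$theta - coarse_step)
  hi <- min(theta_range[2], c_best$theta + coarse_step)
  fine <- eval_grid(setdiff(round(seq(lo, hi, by = fine_step), 12),
                            round(coarse$theta, 12)))
  grid <- rbind(coarse, fine)
  grid <- grid[order(grid$theta), ]
  rownames(grid) <- NULL
  best <- pick(grid)
  structure(list(theta = best$theta, pi0 = best$pi0, sigma2 = best$sigma2,
                 grid = grid, exposure = h$exposure_traits[k],
                 outcome = h$outcome_trait, n_snv = length(bx),
                 standardize = standardize),
            class = "mrmix")
}

#' @export
print.mrmix <- function(x, ...) {
  cat(sprintf("Mixture-model MR: %s -> %s, %d SNVs\n", x$exposure,
              x$outcome, x$n_snv))
  cat(sprintf("  theta = %.3f, pi0 = %.3f, sigma2 = %.3g\n",
              x$theta, x$pi0, x$sigma2))
  invisible(x)
}

#' @export
coef.mrmix <- function(object, ...) {
  c(theta = object$theta, pi0 = object$pi0, sigma2 = object$sigma2)
}
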