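test_that("Wald ratios follow the per-SNV arithmetic", {
  h <- make_hset(bx = c(1, -0.5, 0.2), sx = rep(0.01, 3),
                 by = c(0.1, 0.1, 0.05), sy = c(0.05, 0.05, 0.02))
  r <- wald_ratios(h)
  expect_equal(r$ratio, c(0.1, -0.2, 0.25))
  expect_equal(r$se, c(0.05, 0.1, 0.1))
  expect_equal(r$weight, 1 / r$se^2)

  # element-wise loop oracle on a seeded panel
  set.seed(11)
  h <- make_hset(bx = rnorm(20, 0.1, 0.02), sx = rep(0.01, 20),
                 by = rnorm(20, 0.02, 0.01), sy = runif(20, 0.01, 0.05))
  r <- wald_ratios(h)
  for (j in seq_len(20))
    expect_equal(r$ratio[j], h$by[[j]] / h$bx[[j]])

  # zero exposure beta: excluded with a warning
  h$bx[3, 1] <- 0
  expect_warning(r <- wald_ratios(h), "zero exposure beta")
  expect_equal(nrow(r), 19L)

  # second-order SE dominates the first-order one
  h2 <- make_hset(bx = c(0.1, 0.2, 0.3), sx = rep(0.05, 3),
                  by = c(0.02, 0.03, 0.04), sy = rep(0.01, 3))
  expect_true(all(wald_ratios(h2, se_method = "second")$se >
                  wald_ratios(h2, se_method = "first")$se))
})

test_that("IVW matches the weighted-mean and regression oracles", {
  # hand-checkable panel: ratios {0.2, 0.25, 0.16}, weights {100, 100, 625}
  h <- make_hset(bx = c(1, 1, 1), sx = rep(0.001, 3),
                 by = c(0.2, 0.25, 0.16), sy = c(0.1, 0.1, 0.04))
  fe <- mr_fit(h, method = "ivw_fe")
  expect_equal(fe$beta, 145 / 825, tolerance = 1e-12)
  expect_equal(fe$se, 1 / sqrt(825), tolerance = 1e-12)

  mre <- mr_fit(h, method = "ivw_mre")
  expect_equal(mre$beta, fe$beta)
  q <- 100 * (0.2 - fe$beta)^2 + 100 * (0.25 - fe$beta)^2 +
    625 * (0.16 - fe$beta)^2
  expect_equal(mre$q_stat, q, tolerance = 1e-12)
  expect_equal(mre$se, fe$se * max(1, sqrt(q / 2)), tolerance = 1e-12)

  # identical ratios: no heterogeneity, random SE equals fixed SE
  h0 <- make_hset(bx = c(1, 2, 4), sx = rep(0.001, 3),
                  by = c(0.1, 0.2, 0.4), sy = c(0.05, 0.05, 0.05))
  f0 <- mr_fit(h0, method = "ivw_mre")
  expect_equal(f0$beta, 0.1, tolerance = 1e-12)
  expect_equal(f0$q_stat, 0, tolerance = 1e-9)
  expect_equal(f0$se, mr_fit(h0, method = "ivw_fe")$se)

  # regression oracle: weighted LS of by on bx through the origin with
  # weights 1/sy^2 reproduces the IVW point estimate
  set.seed(21)
  h <- make_hset(bx = rnorm(15, 0.1, 0.03), sx = rep(0.001, 15),
                 by = rnorm(15, 0.03, 0.02), sy = runif(15, 0.01, 0.05))
  ivw <- mr_fit(h, method = "ivw_fe")
  wls <- lm(h$by ~ 0 + h$bx[, 1], weights = 1 / h$sy^2)
  expect_equal(ivw$beta, unname(coef(wls)[1]), tolerance = 1e-10)
})

test_that("median estimators agree with their oracles", {
  h <- make_hset(bx = c(1, 1, 1), sx = rep(0.001, 3),
                 by = c(0.1, 0.2, 0.3), sy = rep(0.05, 3))
  for (m in c("simple_median", "weighted_median", "penalized_median"))
    expect_equal(mr_fit(h, method = m, boot_reps = 50)$beta, 0.2)

  # equal weights collapse the weighted to the simple median
  set.seed(31)
  by <- rnorm(7, 0.1, 0.05)
  h <- make_hset(bx = rep(1, 7), sx = rep(0.001, 7), by = by,
                 sy = rep(0.04, 7))
  expect_equal(mr_fit(h, method = "weighted_median", boot_reps = 50)$beta,
               mr_fit(h, method = "simple_median", boot_reps = 50)$beta)

  # brute-force scan of the interpolated weighted CDF on a 5-SNV panel
  set.seed(32)
  h <- make_hset(bx = rep(1, 5), sx = rep(0.001, 5),
                 by = c(0.05, 0.12, 0.2, 0.3, 0.18),
                 sy = c(0.02, 0.05, 0.03, 0.1, 0.04))
  wm <- mr_fit(h, method = "weighted_median", boot_reps = 50)$beta
  r <- wald_ratios(h)
  o <- order(r$ratio)
  b <- r$ratio[o]; w <- r$weight[o]
  cdf <- function(x) {  # piecewise-linear CDF through the midpoints
    p <- (cumsum(w) - 0.5 * w) / sum(w)
    approx(b, p, xout = x, rule = 2)$y
  }
  xs <- seq(min(b), max(b), length.out = 200001)
  oracle <- xs[which.min(abs(cdf(xs) - 0.5))]
  expect_equal(wm, oracle, tolerance = 1e-4)

  # inactive penalty: penalized equals weighted on a homogeneous panel
  h0 <- make_hset(bx = rep(1, 5), sx = rep(0.001, 5),
                  by = c(0.10, 0.11, 0.10, 0.12, 0.11),
                  sy = rep(0.05, 5))
  expect_equal(mr_fit(h0, method = "penalized_median", boot_reps = 50)$beta,
               mr_fit(h0, method = "weighted_median", boot_reps = 50)$beta)

  # bootstrap SE is seeded and reproducible
  f1 <- mr_fit(h, method = "weighted_median", boot_reps = 200, seed = 9)
  f2 <- mr_fit(h, method = "weighted_median", boot_reps = 200, seed = 9)
  expect_identical(f1$se, f2$se)
  expect_error(mr_fit(make_hset(bx = c(1, 1), sx = rep(0.01, 2),
                                by = c(0.1, 0.2), sy = rep(0.05, 2)),
                      method = "weighted_median"), "at least 3")
})

test_that("Egger regression matches the weighted normal equations", {
  # exact line through the origin: zero intercept, slope equals IVW
  bx <- c(0.05, 0.1, 0.15, 0.2)
  h <- make_hset(bx = bx, sx = rep(0.001, 4), by = 0.3 * bx,
                 sy = rep(0.02, 4))
  # lm warns that the noise-free fixture is an "essentially perfect fit"
  eg <- suppressWarnings(mr_fit(h, method = "egger"))
  expect_equal(eg$beta, 0.3, tolerance = 1e-10)
  expect_equal(eg$egger_intercept, 0, tolerance = 1e-10)

  # translation equivariance: adding c to every by shifts the intercept
  set.seed(41)
  h <- make_hset(bx = runif(8, 0.05, 0.2), sx = rep(0.001, 8),
                 by = rnorm(8, 0.02, 0.01), sy = runif(8, 0.01, 0.03))
  e1 <- mr_fit(h, method = "egger")
  h2 <- h; h2$by <- h$by + 0.05
  e2 <- mr_fit(h2, method = "egger")
  expect_equal(e2$beta, e1$beta, tolerance = 1e-10)
  expect_equal(e2$egger_intercept, e1$egger_intercept + 0.05,
               tolerance = 1e-10)

  # weighted normal-equations oracle
  W <- diag(1 / h$sy^2)
  X <- cbind(1, h$bx[, 1])
  theta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% h$by)
  expect_equal(e1$egger_intercept, theta[1, 1], tolerance = 1e-10)
  expect_equal(e1$beta, theta[2, 1], tolerance = 1e-10)

  expect_error(mr_fit(make_hset(bx = rep(0.1, 4), sx = rep(0.01, 4),
                                by = rep(0.02, 4), sy = rep(0.01, 4)),
                      method = "egger"), "collinear")
})

test_that("Cochran's Q measures heterogeneity about the IVW centre", {
  h <- make_hset(bx = c(1, 2, 4), sx = rep(0.001, 3),
                 by = c(0.1, 0.2, 0.4), sy = rep(0.05, 3))
  r <- wald_ratios(h)
  q0 <- cochran_q(r)
  expect_equal(q0$q_stat, 0, tolerance = 1e-9)
  expect_equal(q0$pval, 1, tolerance = 1e-9)

  h <- make_hset(bx = c(1, 1, 1), sx = rep(0.001, 3),
                 by = c(0.2, 0.25, 0.16), sy = c(0.1, 0.1, 0.04))
  r <- wald_ratios(h)
  q <- cochran_q(r)
  center <- sum(r$weight * r$ratio) / sum(r$weight)
  expect_equal(q$q_stat, sum(r$weight * (r$ratio - center)^2),
               tolerance = 1e-12)
  expect_equal(q$q_stat, 0.765, tolerance = 1e-3)
  expect_equal(q$df, 2L)

  # permutation invariance
  perm <- r[c(3, 1, 2), ]
  attr(perm, "exposure") <- attr(r, "exposure")
  expect_equal(cochran_q(perm)$q_stat, q$q_stat, tolerance = 1e-12)
})

test_that("orientation flips leave every estimator unchanged", {
  set.seed(51)
  J <- 9
  h <- make_hset(bx = rnorm(J, 0.1, 0.04), sx = rep(0.005, J),
                 by = rnorm(J, 0.03, 0.02), sy = runif(J, 0.01, 0.04))
  hf <- h
  flip <- c(2, 5, 7)
  hf$bx[flip, 1] <- -hf$bx[flip, 1]
  hf$by[flip] <- -hf$by[flip]
  for (m in c("ivw_mre", "ivw_fe", "simple_median", "weighted_median",
              "penalized_median", "egger")) {
    f1 <- mr_fit(h, method = m, boot_reps = 100, seed = 3)
    f2 <- mr_fit(hf, method = m, boot_reps = 100, seed = 3)
    expect_equal(f2$beta, f1$beta, tolerance = 1e-10)
    expect_equal(f2$se, f1$se, tolerance = 1e-10)
  }
})

test_that("Bonferroni threshold and significance labels follow the grid", {
  expect_equal(round(bonferroni_threshold(4, 3), 4), 0.0042)
  expect_equal(bonferroni_threshold(4, 3), 0.05 / 12, tolerance = 1e-15)
  expect_equal(bonferroni_threshold(1, 1), 0.05)
  expect_true(all(diff(bonferroni_threshold(1:6, 3)) < 0))

  thr <- bonferroni_threshold(4, 3)
  expect_equal(classify_significance(c(0.001, 0.01, 0.2), thr),
               c("significant", "suggestive", "null"))
})

test_that("mr_fit objects expose coef, confint and printing", {
  h <- make_hset(bx = c(0.05, 0.1, 0.15, 0.2), sx = rep(0.001, 4),
                 by = c(0.015, 0.031, 0.046, 0.059), sy = rep(0.02, 4))
  f <- mr_fit(h, method = "ivw_mre")
  expect_named(coef(f), "beta")
  ci <- confint(f)
  expect_equal(unname(ci["beta", ]),
               c(f$beta - qnorm(0.975) * f$se, f$beta + qnorm(0.975) * f$se))
  expect_output(print(f), "MR estimate")
  expect_true(f$or_ci_low <= f$odds_ratio & f$odds_ratio <= f$or_ci_high)

  tab <- mr_all_methods(h, boot_reps = 50)
  expect_equal(nrow(tab), 6L)
  expect_setequal(unique(tab$method),
                  c("ivw_mre", "ivw_fe", "simple_median", "weighted_median",
                    "penalized_median", "egger"))
})
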