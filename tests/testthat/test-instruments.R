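# Four single-SNV exposure tables with prescribed p-values and effect
# signs (TIBC is the fourth, with direction sign -1).
four_exposures <- function(pvals, signs, rsid = "rs1") {
  traits <- c("iron", "ferritin", "tfsat", "tibc")
  lapply(seq_len(4), function(k) {
    z <- qnorm(pvals[k] / 2, lower.tail = FALSE)
    se <- 0.01
    tiny_table(rsid, beta = signs[k] * z * se, se = se, pval = pvals[k],
               trait = traits[k])
  })
}

test_that("the three selection strategies apply their criteria", {
  # significant everywhere, canonical iron-raising signs: all strategies
  exps <- four_exposures(c(1e-9, 1e-10, 1e-12, 1e-9), c(1, 1, 1, -1))
  expect_equal(select_instruments(exps, 1), "rs1")
  expect_equal(select_instruments(exps, 2), "rs1")
  expect_equal(select_instruments(exps, 3), "rs1")

  # one p above threshold: rejected by strategy 1 only
  exps <- four_exposures(c(1e-9, 1e-9, 1e-9, 1e-7), c(1, 1, 1, -1))
  expect_length(select_instruments(exps, 1), 0L)
  expect_equal(select_instruments(exps, 2), "rs1")
  expect_equal(select_instruments(exps, 3), "rs1")

  # significant once with discordant directions: strategy 3 only
  exps <- four_exposures(c(1e-9, 1e-2, 1e-2, 1e-2), c(1, -1, 1, -1))
  expect_length(select_instruments(exps, 1), 0L)
  expect_length(select_instruments(exps, 2), 0L)
  expect_equal(select_instruments(exps, 3), "rs1")

  expect_error(select_instruments(exps[1:3], 1), "4 exposure tables")
})

test_that("strategies are nested on simulated panels", {
  for (seed in c(2, 9, 31)) {
    st <- simulate_study(synth_config(seed = seed, n_snv = 150,
                                      sd_latent = 0.04,
                                      sd_specific = 0.03))
    s1 <- select_instruments(st$exposures, 1)
    s2 <- select_instruments(st$exposures, 2)
    s3 <- select_instruments(st$exposures, 3)
    expect_true(all(s1 %in% s2))
    expect_true(all(s2 %in% s3))
  }
})

test_that("direction consistency matches the exhaustive sign-pattern oracle", {
  expect_true(is_direction_consistent(c(0.1, 0.2, 0.05, -0.3)))
  expect_false(is_direction_consistent(c(0.1, 0.2, 0.05, 0.3)))
  expect_false(is_direction_consistent(c(0.1, 0, 0.05, -0.3)))

  signs <- c(1, 1, 1, -1)
  grid <- expand.grid(s1 = c(-1, 1), s2 = c(-1, 1), s3 = c(-1, 1),
                      s4 = c(-1, 1))
  for (i in seq_len(nrow(grid))) {
    s <- unlist(grid[i, ])
    betas <- s * c(0.1, 0.2, 0.05, 0.3)
    oracle <- length(unique(sign(betas * signs))) == 1L
    expect_identical(is_direction_consistent(betas, signs), oracle)
  }
})

test_that("clumping keeps the lowest-p SNV per LD cluster", {
  ld <- matrix(c(1, 0.5, 0.5, 1), 2, 2,
               dimnames = list(c("rsA", "rsB"), c("rsA", "rsB")))
  cand <- data.frame(rsid = c("rsA", "rsB"), pval = c(1e-12, 1e-9))
  expect_equal(clump_variants(cand, ld), "rsA")

  # identity LD retains everything
  ld0 <- diag(4)
  dimnames(ld0) <- list(paste0("rs", 1:4), paste0("rs", 1:4))
  cand <- data.frame(rsid = paste0("rs", 1:4), pval = runif(4))
  expect_setequal(clump_variants(cand, ld0), cand$rsid)

  # unknown SNVs are treated as independent, with a warning
  cand <- data.frame(rsid = c("rsA", "rsX"), pval = c(1e-12, 1e-9))
  expect_warning(kept <- clump_variants(cand, ld), "independent")
  expect_setequal(kept, c("rsA", "rsX"))
})

test_that("clumping replays the greedy rule and yields independent sets", {
  st <- simulate_study(synth_config(seed = 13, n_snv = 10,
                                    ld_block_size = 5, ld_decay = 0.8))
  cand <- data.frame(rsid = st$exposures$iron$rsid,
                     pval = st$exposures$iron$pval,
                     pos = st$exposures$iron$pos)
  kept <- clump_variants(cand, st$ld, r2_max = 0.3)

  # independent greedy replay
  ord <- order(cand$pval, cand$pos, cand$rsid)
  oracle <- character(0)
  for (r in cand$rsid[ord]) {
    if (all(st$ld[r, oracle] < 0.3) || length(oracle) == 0L)
      oracle <- c(oracle, r)
  }
  expect_identical(kept, oracle)

  # pairwise independence of the accepted set
  if (length(kept) > 1L) {
    off <- st$ld[kept, kept]
    diag(off) <- 0
    expect_lt(max(off), 0.3)
  }
})

test_that("proxy lookup returns the best qualifying SNV with tie-breaks", {
  rs <- c("rsM", "rsP1", "rsP2", "rsP3")
  ld <- diag(4); dimnames(ld) <- list(rs, rs)
  ld["rsM", "rsP1"] <- ld["rsP1", "rsM"] <- 0.9
  ld["rsM", "rsP2"] <- ld["rsP2", "rsM"] <- 0.85
  expect_equal(find_proxy("rsM", ld, rs[-1]), "rsP1")

  ld["rsM", "rsP1"] <- ld["rsP1", "rsM"] <- 0.7
  ld["rsM", "rsP2"] <- ld["rsP2", "rsM"] <- 0.7
  expect_null(find_proxy("rsM", ld, rs[-1]))

  # exact tie: smaller position, then lexicographic rsid
  ld["rsM", "rsP1"] <- ld["rsP1", "rsM"] <- 0.9
  ld["rsM", "rsP2"] <- ld["rsP2", "rsM"] <- 0.9
  pos <- c(rsP1 = 500, rsP2 = 100, rsP3 = 1)
  expect_equal(find_proxy("rsM", ld, rs[-1], positions = pos), "rsP2")
  pos <- c(rsP1 = 100, rsP2 = 100, rsP3 = 1)
  expect_equal(find_proxy("rsM", ld, rs[-1], positions = pos), "rsP1")
})

test_that("MHC exclusion removes chr6 SNVs with inclusive boundaries", {
  tab <- tiny_table(paste0("rs", 1:5), beta = rep(0.1, 5),
                    se = rep(0.01, 5), chr = "6",
                    pos = c(28477796, 28477797, 30000000, 33448354,
                            33448355))
  kept <- exclude_mhc(tab)
  expect_setequal(kept$rsid, c("rs1", "rs5"))
  expect_setequal(attr(kept, "removed"), c("rs2", "rs3", "rs4"))

  # other chromosomes are untouched at the same coordinates
  tab7 <- tiny_table("rs9", beta = 0.1, se = 0.01, chr = "7",
                     pos = 30000000)
  expect_equal(exclude_mhc(tab7)$rsid, "rs9")
})

test_that("confounder and outcome-association screening removes hits", {
  ann <- data.frame(rsid = c("rs1", "rs2"),
                    trait = c("smoking", "smoking"),
                    pval = c(1e-10, 1e-6))
  out <- tiny_table(c("rs3", "rs4"), beta = c(0.30, 0.001),
                    se = c(0.01, 0.01), trait = "outcome")
  surv <- exclude_pleiotropic(c("rs1", "rs2", "rs3", "rs4"), ann, out)
  expect_setequal(as.character(surv), c("rs2", "rs4"))
  rem <- attr(surv, "removed")
  expect_setequal(rem$rsid, c("rs1", "rs3"))
  expect_true("smoking" %in% rem$trait)

  # set-difference oracle on a seeded synthetic annotation table
  st <- simulate_study(synth_config(seed = 8, n_snv = 60,
                                    n_confounder_snvs = 10))
  cand <- st$exposures$iron$rsid
  surv <- exclude_pleiotropic(cand, st$annotations, st$outcome)
  bad_ann <- st$annotations$rsid[st$annotations$pval < 5e-8]
  bad_out <- st$outcome$rsid[st$outcome$pval < 5e-8]
  expect_setequal(as.character(surv), setdiff(cand, c(bad_ann, bad_out)))
})

test_that("the F statistic follows its closed form and flags weak IVs", {
  expect_equal(f_statistic(0, 1, 1000), 0)
  expect_equal(f_statistic(0.01, 1, 163511), (0.01 / 1) * 163509 / 0.99,
               tolerance = 1e-12)
  expect_equal(round(f_statistic(0.01, 1, 163511), 1), 1651.6)
  expect_error(f_statistic(0.1, 5, 6), "exceed")

  # strictly increasing in r2 and n
  r2s <- seq(0.001, 0.3, length.out = 20)
  expect_true(all(diff(f_statistic(r2s, 1, 5000)) > 0))
  ns <- seq(100, 10000, by = 500)
  expect_true(all(diff(f_statistic(0.01, 1, ns)) > 0))

  expect_lt(f_statistic(0.0001, 1, 50000), 10)  # weak by convention
})

test_that("per-SNV explained variance uses eaf, falling back to z and n", {
  expect_equal(snp_r2(0.1, 0.25), 2 * 0.25 * 0.75 * 0.01)
  # fallback agrees with the z-based approximation
  expect_equal(snp_r2(0.1, NA, se = 0.02, n = 1000),
               25 / (25 + 998))
})

test_that("design-based power matches its closed form and a simulation", {
  # null OR: power collapses to the two-sided tail at the critical value
  p0 <- mr_power(1e5, 0.5, 0.02, 1)$power
  expect_equal(p0, pnorm(-qnorm(0.975)), tolerance = 1e-12)

  # monotone in n, r2 and |ln OR|
  expect_true(all(diff(mr_power(c(1e4, 5e4, 2e5), 0.5, 0.02, 1.2)$power)
                  > 0))
  expect_true(all(diff(mr_power(1e5, 0.5, c(0.005, 0.02, 0.1), 1.2)$power)
                  > 0))
  expect_true(all(diff(mr_power(1e5, 0.5, 0.02, c(1.05, 1.2, 1.5))$power)
                  > 0))

  # Monte-Carlo oracle: rejection rate of the IVW z-test on data
  # simulated at the design point (strong instruments, known bx)
  n <- 5e4; cf <- 0.1; r2 <- 0.015; or <- 1.15; reps <- 5000
  predicted <- mr_power(n, cf, r2, or)$power
  set.seed(401)
  J <- 10
  bx <- rep(sqrt(r2 / J), J)                 # standardized scale
  sy <- rep(1 / sqrt(n * cf * (1 - cf)), J)
  rej <- vapply(seq_len(reps), function(i) {
    by <- rnorm(J, log(or) * bx, sy)
    w <- bx^2 / sy^2
    beta <- sum(w * (by / bx)) / sum(w)
    abs(beta) / (1 / sqrt(sum(w))) > qnorm(0.975)
  }, logical(1))
  mc_se <- sqrt(predicted * (1 - predicted) / reps)
  expect_lt(abs(mean(rej) - predicted), 3 * mc_se)
})
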