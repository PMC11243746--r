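#' Configuration for the synthetic GWAS study generator
#'
#' Defines the study conditions the generator emulates: four biomarker
#' GWAS sharing a latent iron-status factor (TIBC loading negative), a
#' case-control outcome GWAS with a log-odds causal effect of latent iron
#' status, block-structured LD, and an optional fraction of pleiotropic
#' (invalid) instruments with direct outcome effects.  Default sample
#' sizes are the source cohorts scaled down tenfold (serum iron 16,351;
#' ferritin 24,614; TfSat 13,147; TIBC 13,543; outcome 65,314 with case
#' fraction 0.024) so a full analysis runs in seconds.
#'
#' @param seed integer seed; the same seed reproduces byte-identical
#'   output.
#' @param n_snv number of SNVs.
#' @param ld_block_size SNVs per LD block.
#' @param ld_decay within-block correlation decay in `[0, 1)`;
#'   `r^2 = ld_decay^(2 * distance)`.
#' @param maf_range minor-allele-frequency interval within (0, 0.5].
#' @param n_iron,n_ferritin,n_tfsat,n_tibc exposure GWAS sample sizes.
#' @param n_outcome,case_fraction outcome GWAS design.
#' @param theta true causal effect: a scalar log-OR per SD of latent
#'   iron status, or a length-4 vector of per-biomarker log-OR effects.
#' @param factor_loadings signed loadings of the four biomarkers on the
#'   latent factor (default `c(1, 1, 1, -1)`: TIBC inverted).
#' @param sd_latent SD of the per-SNV latent iron-status effect
#'   (SD units of the biomarkers; 0 gives a null GWAS).
#' @param sd_specific SD of biomarker-specific genetic effects on top of
#'   the shared factor (decorrelates the four exposures).
#' @param invalid_fraction share of SNVs with direct (pleiotropic)
#'   outcome effects.
#' @param sigma_pleio SD of those direct effects (log-odds).
#' @param n_confounder_snvs SNVs annotated to confounder traits at
#'   genome-wide significance in the annotation table.
#' @return object of class `synth_config` (a validated list).
#' @export
synth_config <- function(seed = 1L, n_snv = 120L, ld_block_size = 4L,
                         ld_decay = 0.5, maf_range = c(0.05, 0.5),
                         n_iron = 16351L, n_ferritin = 24614L,
                         n_tfsat = 13147L, n_tibc = 13543L,
                         n_outcome = 65314L, case_fraction = 0.024,
                         theta = 0.1,
                         factor_loadings = c(iron = 1, ferritin = 1,
                                             tfsat = 1, tibc = -1),
                         sd_latent = 0.05, sd_specific = 0.02,
                         invalid_fraction = 0, sigma_pleio = 0.05,
                         n_confounder_snvs = 5L) {
  cfg <- list(seed = as.integer(seed), n_snv = as.integer(n_snv),
              ld_block_size = as.integer(ld_block_size),
              ld_decay = ld_decay, maf_range = maf_range,
              n_iron = n_iron, n_ferritin = n_ferritin,
              n_tfsat = n_tfsat, n_tibc = n_tibc,
              n_outcome = n_outcome, case_fraction = case_fraction,
              theta = theta, factor_loadings = factor_loadings,
              sd_latent = sd_latent, sd_specific = sd_specific,
              invalid_fraction = invalid_fraction,
              sigma_pleio = sigma_pleio,
              n_confounder_snvs = as.integer(n_confounder_snvs))
  stopifnot(cfg$n_snv >= 1, cfg$ld_block_size >= 1,
            cfg$ld_decay >= 0, cfg$ld_decay < 1,
            length(cfg$maf_range) == 2, cfg$maf_range[1] > 0,
            cfg$maf_range[2] <= 0.5,
            cfg$case_fraction > 0, cfg$case_fraction < 1,
            length(cfg$theta) %in% c(1L, 4L),
            length(cfg$factor_loadings) == 4L,
            cfg$invalid_fraction >= 0, cfg$invalid_fraction <= 1,
            cfg$sd_latent >= 0, cfg$sd_specific >= 0,
            cfg$sigma_pleio >= 0)
  structure(cfg, class = "synth_config")
}

.exposure_names <- c("iron", "ferritin", "tfsat", "tibc")

#' Simulate a complete two-sample MR study
#'
#' Generates four exposure GWAS, one case-control outcome GWAS, a
#' block-diagonal LD (r-squared) matrix and a confounder annotation
#' table, all deterministic given `cfg$seed`, plus a truth record of
#' every latent quantity for recovery tests.
#'
#' Per SNV: a minor-allele frequency is drawn on `maf_range`; a latent
#' iron-status effect `gamma ~ N(0, sd_latent^2)`; biomarker true betas
#' are `loading_k * gamma` plus a biomarker-specific
#' `N(0, sd_specific^2)` deviation; the true outcome log-odds effect is
#' `theta * gamma` (or `sum_k theta_k * beta_k` for a length-4 `theta`)
#' plus a direct effect `N(0, sigma_pleio^2)` for the invalid fraction.
#' Observed betas add sampling noise with the analytic standard errors
#' `se = (2 f (1 - f) n)^(-1/2)` for the continuous biomarkers and
#' `se = (2 f (1 - f) n cf (1 - cf))^(-1/2)` for the case-control
#' outcome.
#'
#' @param cfg a [synth_config()].
#' @return object of class `synth_study`: list with `exposures` (named
#'   list of four [gwas_table()]s), `outcome`, `ld`, `annotations`,
#'   `truth` (data frame) and `config`.
#' @export
simulate_study <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  withr_seed(cfg$seed, {
    J <- cfg$n_snv
    rsid <- sprintf("rs%06d", seq_len(J) * 7L + 1000L)
    chr <- as.character(rep_len(c(1:5, 7:12), J))
    pos <- seq_len(J) * 50000L + 123L
    maf <- runif(J, cfg$maf_range[1], cfg$maf_range[2])
    gamma <- rnorm(J, 0, cfg$sd_latent)
    eta <- matrix(rnorm(J * 4L, 0, cfg$sd_specific), J, 4L)
    beta_x_true <- sweep(matrix(gamma, J, 4L), 2, cfg$factor_loadings, "*") +
      eta
    colnames(beta_x_true) <- .exposure_names
    invalid <- rep(FALSE, J)
    n_invalid <- round(cfg$invalid_fraction * J)
    if (n_invalid > 0) invalid[sample.int(J, n_invalid)] <- TRUE
    alpha <- ifelse(invalid, rnorm(J, 0, cfg$sigma_pleio), 0)
    beta_y_true <- if (length(cfg$theta) == 1L)
      cfg$theta * gamma + alpha
    else
      drop(beta_x_true %*% cfg$theta) + alpha

    n_exp <- c(cfg$n_iron, cfg$n_ferritin, cfg$n_tfsat, cfg$n_tibc)
    exposures <- vector("list", 4L)
    names(exposures) <- .exposure_names
    for (k in 1:4) {
      se <- 1 / sqrt(2 * maf * (1 - maf) * n_exp[k])
      beta <- beta_x_true[, k] + rnorm(J, 0, se)
      exposures[[k]] <- gwas_table(data.frame(
        rsid = rsid, chr = chr, pos = pos, ea = "A", oa = "G",
        eaf = maf, beta = beta, se = se,
        pval = pmax(2 * pnorm(-abs(beta / se)), 1e-300), n = n_exp[k],
        stringsAsFactors = FALSE), trait = .exposure_names[k])
    }
    cf <- cfg$case_fraction
    se_y <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_outcome * cf * (1 - cf))
    by <- beta_y_true + rnorm(J, 0, se_y)
    outcome <- gwas_table(data.frame(
      rsid = rsid, chr = chr, pos = pos, ea = "A", oa = "G",
      eaf = maf, beta = by, se = se_y,
      pval = pmax(2 * pnorm(-abs(by / se_y)), 1e-300), n = cfg$n_outcome,
      stringsAsFactors = FALSE), trait = "outcome")

    ld <- .block_ld(rsid, cfg$ld_block_size, cfg$ld_decay)

    ann <- data.frame(rsid = character(), trait = character(),
                      pval = numeric(), stringsAsFactors = FALSE)
    if (cfg$n_confounder_snvs > 0) {
      conf_snvs <- rsid[sample.int(J, min(cfg$n_confounder_snvs, J))]
      ann <- data.frame(
        rsid = conf_snvs,
        trait = rep_len(c("smoking", "body_mass_index",
                          "alcohol_intake"), length(conf_snvs)),
        pval = 10^runif(length(conf_snvs), -30, -9),
        stringsAsFactors = FALSE)
    }
    # benign annotations above threshold, to exercise the filter
    ann <- rbind(ann, data.frame(rsid = rsid[seq_len(min(3L, J))],
                                 trait = "height",
                                 pval = 10^runif(min(3L, J), -6, -2),
                                 stringsAsFactors = FALSE))

    truth <- data.frame(rsid = rsid, chr = chr, pos = pos, maf = maf,
                        gamma = gamma, beta_y_true = beta_y_true,
                        alpha = alpha, invalid = invalid,
                        stringsAsFactors = FALSE)
    truth <- cbind(truth, setNames(as.data.frame(beta_x_true),
                                   paste0("beta_", .exposure_names)))

    structure(list(exposures = exposures, outcome = outcome, ld = ld,
                   annotations = ann, truth = truth, config = cfg),
              class = "synth_study")
  })
}

# Block-diagonal LD: within a block, correlation decays as
# ld_decay^distance (AR(1), positive semidefinite), and r^2 is its
# elementwise square (a Schur product of PSD matrices, hence PSD).
.block_ld <- function(rsid, block_size, decay) {
  J <- length(rsid)
  r2 <- matrix(0, J, J, dimnames = list(rsid, rsid))
  block <- (seq_len(J) - 1L) %/% block_size
  for (b in unique(block)) {
    i <- which(block == b)
    d <- abs(outer(seq_along(i), seq_along(i), "-"))
    r2[i, i] <- (decay^d)^2
  }
  diag(r2) <- 1
  r2
}

#' @export
print.synth_study <- function(x, ...) {
  cat(sprintf("Synthetic two-sample MR study: %d SNVs, seed %d\n",
              x$config$n_snv, x$config$seed))
  cat(sprintf("  true theta: %s; invalid fraction %.2f\n",
              paste(format(x$config$theta), collapse = ", "),
              x$config$invalid_fraction))
  invisible(x)
}

#' Fixture study targeting one instrument-selection strategy
#'
#' Plants noise-free SNVs whose observed effects are fixed multiples of
#' their standard errors so that each planted SNV satisfies exactly one
#' selection tier: `strong` SNVs pass all three strategies, `partial`
#' SNVs (one significant biomarker, consistent directions) pass
#' strategies 2 and 3 only, and `discordant` SNVs (one significant
#' biomarker, inconsistent directions) pass strategy 3 only.  Background
#' null SNVs pass none.  Used to exercise the selection logic with known
#' ground truth.
#'
#' @param cfg a [synth_config()]; its sample sizes, MAF range and LD
#'   settings are reused.
#' @param n_strong,n_partial,n_discordant,n_null counts of each planted
#'   class.
#' @return a `synth_study` whose `truth` carries a `class` column
#'   (`strong`/`partial`/`discordant`/`null`) and whose observed tables
#'   are deterministic given `cfg$seed`.
#' @export
make_strategy_fixture <- function(cfg = synth_config(), n_strong = 3L,
                                  n_partial = 3L, n_discordant = 3L,
                                  n_null = 6L) {
  withr_seed(cfg$seed, {
    J <- n_strong + n_partial + n_discordant + n_null
    cls <- rep(c("strong", "partial", "discordant", "null"),
               c(n_strong, n_partial, n_discordant, n_null))
    rsid <- sprintf("rs%06d", seq_len(J) * 11L + 5000L)
    chr <- as.character(rep_len(c(1:5, 7:12), J))
    pos <- seq_len(J) * 60000L + 321L
    maf <- runif(J, cfg$maf_range[1], cfg$maf_range[2])
    n_exp <- c(cfg$n_iron, cfg$n_ferritin, cfg$n_tfsat, cfg$n_tibc)
    # z-multiples: 8 se is decisively significant (p ~ 1e-15), 2 se is
    # decisively not (p ~ 0.05)
    z_hi <- 8; z_lo <- 2
    exposures <- vector("list", 4L)
    names(exposures) <- .exposure_names
    sgn <- cfg$factor_loadings
    for (k in 1:4) {
      se <- 1 / sqrt(2 * maf * (1 - maf) * n_exp[k])
      z <- numeric(J)
      z[cls == "strong"] <- z_hi * sgn[k]
      z[cls == "partial"] <- (if (k == 1) z_hi else z_lo) * sgn[k]
      z[cls == "discordant"] <- if (k == 1) z_hi * sgn[k] else
        z_lo * sgn[k] * (-1)^k
      z[cls == "null"] <- 0.5 * sgn[k]
      beta <- z * se
      exposures[[k]] <- gwas_table(data.frame(
        rsid = rsid, chr = chr, pos = pos, ea = "A", oa = "G",
        eaf = maf, beta = beta, se = se,
        pval = pmax(2 * pnorm(-abs(z)), 1e-300), n = n_exp[k],
        stringsAsFactors = FALSE), trait = .exposure_names[k])
    }
    cf <- cfg$case_fraction
    se_y <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_outcome * cf * (1 - cf))
    th <- if (length(cfg$theta) == 1L) cfg$theta else mean(cfg$theta)
    by <- th * exposures[[1]]$beta
    outcome <- gwas_table(data.frame(
      rsid = rsid, chr = chr, pos = pos, ea = "A", oa = "G",
      eaf = maf, beta = by, se = se_y,
      pval = pmax(2 * pnorm(-abs(by / se_y)), 1e-300), n = cfg$n_outcome,
      stringsAsFactors = FALSE), trait = "outcome")
    truth <- data.frame(rsid = rsid, class = cls, maf = maf,
                        stringsAsFactors = FALSE)
    structure(list(exposures = exposures, outcome = outcome,
                   ld = .block_ld(rsid, cfg$ld_block_size, cfg$ld_decay),
                   annotations = data.frame(rsid = character(),
                                            trait = character(),
                                            pval = numeric()),
                   truth = truth, config = cfg),
              class = "synth_study")
  })
}
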