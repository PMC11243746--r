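#' Assemble a run configuration
#'
#' Collects every input path and threshold the pipeline uses.  All
#' thresholds default to the published analysis settings: genome-wide
#' significance `5e-8`, clumping `r^2 < 0.01`, proxies at `r^2 >= 0.8`,
#' the classical MHC interval on chromosome 6 (GRCh37), Bonferroni
#' correction over 4 exposures x 3 outcomes.
#'
#' @param exposure_paths named character vector (or list) of the four
#'   exposure summary-statistic TSVs, or `NULL` when tables are supplied
#'   in memory to [run_full_analysis()].
#' @param outcome_path outcome TSV path (or `NULL`).
#' @param ld_path LD matrix TSV path (or `NULL`).
#' @param annotation_path annotation TSV path (or `NULL`).
#' @param strategy instrument-selection strategy, 1, 2 or 3.
#' @param p_threshold genome-wide significance threshold.
#' @param clump_r2 clumping independence threshold.
#' @param proxy_r2 minimum proxy r-squared.
#' @param mhc_region list `chrom`/`start`/`end`.
#' @param palindrome_maf_cut see [harmonize()].
#' @param n_exposures,n_outcomes,alpha Bonferroni inputs.
#' @param boot_reps,penalty,prior_incl,prior_sd,theta_range method
#'   settings passed through to the estimators.
#' @param seed seed for the bootstrap.
#' @param output_dir where result TSVs are written (`NULL`: nowhere).
#' @return object of class `run_config` (a list).
#' @export
run_config <- function(exposure_paths = NULL, outcome_path = NULL,
                       ld_path = NULL, annotation_path = NULL,
                       strategy = 1L, p_threshold = 5e-8,
                       clump_r2 = 0.01, proxy_r2 = 0.8,
                       mhc_region = list(chrom = "6", start = 28477797,
                                         end = 33448354),
                       palindrome_maf_cut = 0.42,
                       n_exposures = 4L, n_outcomes = 3L, alpha = 0.05,
                       boot_reps = 1000L, penalty = 20,
                       prior_incl = 0.5, prior_sd = 0.25,
                       theta_range = c(-0.5, 0.5), seed = 1L,
                       output_dir = NULL) {
  cfg <- list(exposure_paths = exposure_paths, outcome_path = outcome_path,
              ld_path = ld_path, annotation_path = annotation_path,
              strategy = as.integer(strategy), p_threshold = p_threshold,
              clump_r2 = clump_r2, proxy_r2 = proxy_r2,
              mhc_region = mhc_region,
              palindrome_maf_cut = palindrome_maf_cut,
              n_exposures = n_exposures, n_outcomes = n_outcomes,
              alpha = alpha, boot_reps = as.integer(boot_reps),
              penalty = penalty, prior_incl = prior_incl,
              prior_sd = prior_sd, theta_range = theta_range,
              seed = as.integer(seed), output_dir = output_dir)
  stopifnot(cfg$strategy %in% 1:3, cfg$p_threshold > 0,
            cfg$clump_r2 > 0, cfg$clump_r2 < 1,
            cfg$proxy_r2 > 0, cfg$proxy_r2 <= 1,
            cfg$alpha > 0, cfg$alpha < 1)
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' The configuration round-trips losslessly, so a run is fully described
#' by its config file plus the input tables.
#'
#' @param path YAML file path.
#' @return for `read_run_config`, a [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param cfg a [run_config()].
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full two-sample MR analysis
#'
#' Executes the published pipeline end to end: instrument selection under
#' the configured strategy, proxy substitution for SNVs missing from the
#' outcome data, MHC and confounder/outcome-association exclusion, LD
#' clumping, harmonization, per-SNV F statistics, every univariable
#' estimator for every biomarker, Cochran's Q and Egger-intercept
#' sensitivity analyses, the mixture-model estimator, and multivariable
#' MR by Bayesian model averaging with instrument diagnostics.  All
#' stages are deterministic given the inputs and `cfg$seed`.
#'
#' @param cfg a [run_config()]; its paths are read unless tables are
#'   given directly.
#' @param exposures optional named list of four exposure
#'   [gwas_table()]s (overrides `cfg$exposure_paths`).
#' @param outcome optional outcome [gwas_table()].
#' @param ld optional LD r-squared matrix.
#' @param annotations optional annotation data frame.
#' @return object of class `iron_mr_analysis`: list with `instruments`
#'   (selection report), `harmonized`, `strength` (per-SNV F), `power`,
#'   `estimates` (tidy per-method table with significance labels),
#'   `heterogeneity`, `mrmix` (per-exposure data frame), `bma`
#'   ([mr_bma()] object), `bma_factors`, `bma_models`, `diagnostics`,
#'   `log` (character vector), `config`.  When `cfg$output_dir` is set
#'   the tables are also written there as TSVs.
#' @export
run_full_analysis <- function(cfg = run_config(), exposures = NULL,
                              outcome = NULL, ld = NULL,
                              annotations = NULL) {
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  if (is.null(exposures)) {
    if (is.null(cfg$exposure_paths)) stop("no exposure tables supplied")
    exposures <- lapply(names(cfg$exposure_paths), function(tr)
      read_sumstats(cfg$exposure_paths[[tr]], trait = tr))
    names(exposures) <- names(cfg$exposure_paths)
  }
  if (is.null(outcome)) {
    if (is.null(cfg$outcome_path)) stop("no outcome table supplied")
    outcome <- read_sumstats(cfg$outcome_path, trait = "outcome")
  }
  if (is.null(ld) && !is.null(cfg$ld_path)) ld <- read_ld_matrix(cfg$ld_path)
  if (is.null(annotations) && !is.null(cfg$annotation_path))
    annotations <- read_annotations(cfg$annotation_path)
  if (length(exposures) != 4L)
    stop("stage selection: exactly 4 exposure tables required")

  fate <- list()
  note <- function(rsids, f) {
    for (r in rsids) if (is.null(fate[[r]])) fate[[r]] <<- f
  }

  ## --- selection ---------------------------------------------------
  sel <- select_instruments(exposures, cfg$strategy, cfg$p_threshold)
  say("selection: strategy %d retained %d of %d candidate SNVs",
      cfg$strategy, length(sel), nrow(exposures[[1]]))
  note(setdiff(exposures[[1]]$rsid, sel), "not_selected")
  if (length(sel) == 0L) stop("stage selection: no instruments selected")

  ## --- proxy substitution for SNVs missing in the outcome ----------
  missing_out <- setdiff(sel, outcome$rsid)
  if (length(missing_out) > 0L && !is.null(ld)) {
    pos <- setNames(exposures[[1]]$pos, exposures[[1]]$rsid)
    for (m in missing_out) {
      avail <- intersect(outcome$rsid, exposures[[1]]$rsid)
      pr <- find_proxy(m, ld, setdiff(avail, sel), cfg$proxy_r2, pos)
      if (!is.null(pr)) {
        sel[sel == m] <- pr
        note(m, "proxied")
        say("proxy: %s replaced by %s", m, pr)
      } else {
        sel <- setdiff(sel, m)
        note(m, "no_proxy")
        say("proxy: none found for %s at r2 >= %g, SNV dropped", m,
            cfg$proxy_r2)
      }
    }
  } else if (length(missing_out) > 0L) {
    sel <- setdiff(sel, missing_out)
    note(missing_out, "absent_from_outcome")
  }

  ## --- MHC exclusion ------------------------------------------------
  cand <- as.data.frame(exposures[[1]])[match(sel, exposures[[1]]$rsid), ]
  kept <- exclude_mhc(cand, cfg$mhc_region)
  note(attr(kept, "removed"), "mhc")
  say("mhc: removed %d SNV(s)", length(attr(kept, "removed")))
  sel <- kept$rsid

  ## --- confounder / outcome-association exclusion ------------------
  surv <- exclude_pleiotropic(sel, annotations, outcome, cfg$p_threshold)
  rem <- attr(surv, "removed")
  if (nrow(rem) > 0L) {
    note(rem$rsid, "pleiotropic")
    say("pleiotropy screen: removed %d SNV(s): %s", length(unique(rem$rsid)),
        paste(unique(rem$rsid), collapse = ", "))
  }
  sel <- as.character(surv)

  ## --- clumping ------------------------------------------------------
  if (!is.null(ld) && length(sel) > 1L) {
    pmin_ <- do.call(pmin, lapply(exposures, function(e)
      e$pval[match(sel, e$rsid)]))
    cand <- data.frame(rsid = sel, pval = pmin_,
                       pos = exposures[[1]]$pos[match(sel,
                                                      exposures[[1]]$rsid)])
    clumped <- clump_variants(cand, ld, cfg$clump_r2)
    note(setdiff(sel, clumped), "clumped")
    say("clumping: %d -> %d independent SNV(s)", length(sel),
        length(clumped))
    sel <- clumped
  }
  if (length(sel) == 0L) stop("stage clumping: no instruments left")

  ## --- harmonization -------------------------------------------------
  h <- harmonize(exposures, outcome, cfg$palindrome_maf_cut, snps = sel)
  if (nrow(h$dropped) > 0L) {
    note(h$dropped$rsid, "harmonization_dropped")
    say("harmonization: dropped %d SNV(s)", nrow(h$dropped))
  }
  note(h$rsids, "instrument")
  say("harmonization: %d instrument(s) on common orientation", length(h$rsids))
  if (length(h$rsids) == 0L) stop("stage harmonization: no instruments left")

  ## --- instrument strength and power ---------------------------------
  strength <- do.call(rbind, lapply(seq_along(h$exposure_traits),
                                    function(k) {
    r2 <- snp_r2(h$bx[, k], h$eaf, h$sx[, k], h$nx[, k])
    data.frame(exposure = h$exposure_traits[k], rsid = h$rsids, r2 = r2,
               f_stat = f_statistic(r2, 1L, h$nx[, k]),
               weak = f_statistic(r2, 1L, h$nx[, k]) < 10,
               stringsAsFactors = FALSE)
  }))
  power <- do.call(rbind, lapply(seq_along(h$exposure_traits),
                                 function(k) {
    r2s <- sum(snp_r2(h$bx[, k], h$eaf, h$sx[, k], h$nx[, k]))
    cbind(exposure = h$exposure_traits[k],
          mr_power(n_outcome = max(h$ny), case_fraction = 0.5,
                   r2_sum = r2s, odds_ratio = 1.2, alpha = cfg$alpha))
  }))

  ## --- univariable estimators ---------------------------------------
  est <- mr_all_methods(h, boot_reps = cfg$boot_reps, seed = cfg$seed,
                        penalty = cfg$penalty)
  thr <- bonferroni_threshold(cfg$n_exposures, cfg$n_outcomes, cfg$alpha)
  est$significance <- classify_significance(est$pval, thr, cfg$alpha)
  say("estimators: %d fits, Bonferroni threshold %.4g", nrow(est), thr)

  het <- do.call(rbind, lapply(seq_along(h$exposure_traits), function(k) {
    r <- wald_ratios(h, k)
    q_ivw <- cochran_q(r)
    eg <- mr_fit(h, k, method = "egger")
    data.frame(exposure = h$exposure_traits[k],
               q_ivw = q_ivw$q_stat, q_ivw_df = q_ivw$df,
               q_ivw_pval = q_ivw$pval,
               q_egger = eg$q_stat, q_egger_df = eg$q_df,
               q_egger_pval = pchisq(eg$q_stat, eg$q_df,
                                     lower.tail = FALSE),
               egger_intercept = eg$egger_intercept,
               intercept_pval = eg$intercept_pval,
               stringsAsFactors = FALSE)
  }))

  ## --- mixture model --------------------------------------------------
  mix <- NULL
  if (length(h$rsids) >= 4L) {
    mix <- do.call(rbind, lapply(seq_along(h$exposure_traits),
                                 function(k) {
      m <- mrmix(h, k, theta_range = cfg$theta_range)
      data.frame(exposure = m$exposure, outcome = m$outcome,
                 theta = m$theta, pi0 = m$pi0, sigma2 = m$sigma2,
                 stringsAsFactors = FALSE)
    }))
    say("mixture model: fitted %d exposure(s)", nrow(mix))
  } else say("mixture model: skipped, fewer than 4 instruments")

  ## --- multivariable MR ----------------------------------------------
  bma <- NULL; bma_factors <- NULL; bma_models <- NULL; diagnostics <- NULL
  if (length(h$rsids) > ncol(h$bx)) {
    bma <- mr_bma(h, cfg$prior_incl, cfg$prior_sd)
    rank <- order(-bma$mip)
    bma_factors <- data.frame(risk_factor = names(bma$mip)[rank],
                              mip = unname(bma$mip[rank]),
                              theta_mace = unname(bma$theta_mace[rank]),
                              stringsAsFactors = FALSE)
    m <- bma$models[bma$models$members != "", , drop = FALSE]
    bma_models <- utils::head(m[, c("members", "pp", "theta")], 10L)
    diagnostics <- bma$diagnostics
    say("model averaging: top factor %s (MIP %.3f)",
        bma_factors$risk_factor[1], bma_factors$mip[1])
  } else say("model averaging: skipped, J <= K")

  fate_df <- data.frame(rsid = names(fate),
                        fate = unlist(fate, use.names = FALSE),
                        stringsAsFactors = FALSE)

  out <- structure(list(instruments = fate_df, harmonized = h,
                        strength = strength, power = power,
                        estimates = est, heterogeneity = het,
                        mrmix = mix, bma = bma,
                        bma_factors = bma_factors,
                        bma_models = bma_models,
                        diagnostics = diagnostics,
                        bonferroni = thr, log = log, config = cfg),
                   class = "iron_mr_analysis")
  if (!is.null(cfg$output_dir)) .write_analysis(out, cfg$output_dir)
  out
}

.write_analysis <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, name) {
    if (!is.null(df))
      utils::write.table(df, file.path(dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  wt(x$estimates, "estimates.tsv")
  wt(x$heterogeneity, "heterogeneity.tsv")
  wt(x$mrmix, "mrmix.tsv")
  wt(x$bma_factors, "bma_factors.tsv")
  wt(x$bma_models, "bma_models.tsv")
  wt(x$diagnostics, "bma_diagnostics.tsv")
  wt(x$strength, "instrument_strength.tsv")
  wt(x$power, "power.tsv")
  wt(x$instruments, "selection_report.tsv")
  wt(x$harmonized$dropped, "harmonization_drops.tsv")
  writeLines(x$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.iron_mr_analysis <- function(x, ...) {
  cat("Two-sample MR analysis of systemic iron status\n")
  cat(sprintf("  strategy %d, %d instrument(s), Bonferroni %.4g\n",
              x$config$strategy, length(x$harmonized$rsids),
              x$bonferroni))
  ivw <- x$estimates[x$estimates$method == "ivw_mre", ]
  cat("  multiplicative random-effect IVW:\n")
  for (i in seq_len(nrow(ivw)))
    cat(sprintf("    %-10s OR %.2f [%.2f, %.2f]  p %.3g  (%s)\n",
                ivw$exposure[i], ivw$or[i], ivw$ci_low[i], ivw$ci_high[i],
                ivw$pval[i], ivw$significance[i]))
  invisible(x)
}
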