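#' Select instrumental SNVs under one of three strategies
#'
#' Candidate instruments for systemic iron status are chosen from the four
#' biomarker GWAS under three nested strategies:
#' \describe{
#'   \item{1}{genome-wide significant (`p < p_threshold`) in all four
#'     biomarkers, with direction-consistent effects on iron status;}
#'   \item{2}{significant in at least one biomarker and
#'     direction-consistent in all four (see
#'     [is_direction_consistent()]);}
#'   \item{3}{significant in at least one biomarker.}
#' }
#' Direction consistency accounts for total iron-binding capacity varying
#' inversely with iron status (direction sign -1).  Betas are compared on
#' the first exposure's effect-allele orientation; candidate SNVs whose
#' alleles cannot be reconciled across the four tables are skipped.
#'
#' Strategy 1 also requires direction consistency so that the strategies
#' are nested (every strategy-1 instrument is a strategy-2 instrument).
#'
#' @param exposures list of exactly four exposure [gwas_table()]s.
#' @param strategy 1, 2 or 3.
#' @param p_threshold genome-wide significance threshold
#'   (default `5e-8`).
#' @return character vector of selected rsIDs (in first-exposure order).
#' @export
select_instruments <- function(exposures, strategy, p_threshold = 5e-8) {
  if (length(exposures) != 4L)
    stop("exactly 4 exposure tables are required, got ", length(exposures))
  strategy <- match.arg(as.character(strategy), c("1", "2", "3"))
  signs <- vapply(exposures, function(e) attr(e, "direction_sign") %||% 1,
                  numeric(1))
  common <- Reduce(intersect, lapply(exposures, function(t) t$rsid))
  common <- exposures[[1]]$rsid[exposures[[1]]$rsid %in% common]
  ref <- as.data.frame(exposures[[1]])[match(common, exposures[[1]]$rsid), ]
  B <- P <- matrix(NA_real_, length(common), 4L)
  keep <- rep(TRUE, length(common))
  for (k in 1:4) {
    tab <- as.data.frame(exposures[[k]])[match(common, exposures[[k]]$rsid), ]
    for (j in seq_along(common)) {
      al <- .align_alleles(tab$ea[j], tab$oa[j], tab$eaf[j],
                           ref$ea[j], ref$oa[j], ref$eaf[j], maf_cut = 0.5)
      if (al$action == "drop") { keep[j] <- FALSE; next }
      B[j, k] <- if (al$action == "flip") -tab$beta[j] else tab$beta[j]
      P[j, k] <- tab$pval[j]
    }
  }
  sig <- P < p_threshold
  consistent <- vapply(seq_along(common), function(j)
    keep[j] && is_direction_consistent(B[j, ], signs), logical(1))
  chosen <- switch(strategy,
    "1" = keep & apply(sig, 1L, all) & consistent,
    "2" = keep & apply(sig, 1L, any) & consistent,
    "3" = keep & apply(sig, 1L, any))
  chosen[is.na(chosen)] <- FALSE
  common[chosen]
}

#' Direction consistency of a SNV across the four iron biomarkers
#'
#' TRUE when every biomarker effect points the same way on the iron-status
#' axis, i.e. `sign(beta_k * direction_sign_k)` is identical for all k
#' (TIBC carries direction sign -1).  A beta of exactly zero is
#' indeterminate and treated as inconsistent.
#'
#' @param betas numeric vector of four signed effects on a common allele
#'   orientation.
#' @param direction_signs vector of +1/-1 per biomarker
#'   (default `c(1, 1, 1, -1)`).
#' @return logical scalar.
#' @export
is_direction_consistent <- function(betas, direction_signs = c(1, 1, 1, -1)) {
  stopifnot(length(betas) == length(direction_signs))
  if (anyNA(betas) || any(betas == 0)) return(FALSE)
  s <- sign(betas * direction_signs)
  all(s == s[1])
}

#' Greedy LD clumping
#'
#' Sorts candidates by ascending p-value (ties broken by smaller base
#' position, then lexicographic rsID) and accepts a SNV iff its squared
#' correlation with every already-accepted SNV is below `r2_max`.
#' SNVs absent from the LD matrix are treated as independent, with a
#' warning.
#'
#' @param candidates data frame with columns `rsid`, `pval` and
#'   optionally `pos`.
#' @param ld square r-squared matrix with rsID dimnames (see
#'   [read_ld_matrix()]).
#' @param r2_max independence threshold (default 0.01).
#' @return character vector of retained rsIDs in acceptance order.
#' @export
clump_variants <- function(candidates, ld, r2_max = 0.01) {
  stopifnot(is.data.frame(candidates), all(c("rsid", "pval") %in%
                                           names(candidates)))
  pos <- if ("pos" %in% names(candidates)) candidates$pos else
    rep(0, nrow(candidates))
  ord <- order(candidates$pval, pos, candidates$rsid)
  rsid <- candidates$rsid[ord]
  unknown <- setdiff(rsid, rownames(ld))
  if (length(unknown) > 0L)
    warning("rsid(s) absent from LD matrix, treated as independent: ",
            paste(unknown, collapse = ", "))
  accepted <- character(0)
  for (r in rsid) {
    indep <- TRUE
    if (r %in% rownames(ld) && length(accepted) > 0L) {
      others <- intersect(accepted, colnames(ld))
      if (length(others) > 0L && any(ld[r, others] >= r2_max))
        indep <- FALSE
    }
    if (indep) accepted <- c(accepted, r)
  }
  accepted
}

#' Find an LD proxy for a missing SNV
#'
#' Returns the available SNV with the highest squared correlation
#' (at least `r2_min`) to the missing SNV; ties are broken by smaller
#' base position, then lexicographic rsID.
#'
#' @param missing rsID absent from the outcome data.
#' @param ld square r-squared matrix with rsID dimnames.
#' @param available character vector of candidate proxy rsIDs.
#' @param r2_min minimum r-squared (default 0.8).
#' @param positions optional named vector of base positions used for
#'   tie-breaking.
#' @return the proxy rsID, or `NULL` when none qualifies.
#' @export
find_proxy <- function(missing, ld, available, r2_min = 0.8,
                       positions = NULL) {
  available <- setdiff(available, missing)
  available <- intersect(available, colnames(ld))
  if (!(missing %in% rownames(ld)) || length(available) == 0L) return(NULL)
  r2 <- ld[missing, available]
  qual <- available[r2 >= r2_min]
  if (length(qual) == 0L) return(NULL)
  r2q <- r2[r2 >= r2_min]
  pos <- if (is.null(positions)) rep(0, length(qual)) else
    ifelse(is.na(positions[qual]), Inf, positions[qual])
  qual[order(-r2q, pos, qual)][1]
}

#' Remove SNVs inside the MHC region
#'
#' The extended LD of the major histocompatibility complex on chromosome 6
#' (GRCh37) makes instruments there unreliable; SNVs inside the region
#' (inclusive ends) are removed.
#'
#' @param candidates data frame with columns `rsid`, `chr`, `pos`
#'   (e.g. a [gwas_table()]).
#' @param region list/vector with `chrom`, `start`, `end`; default the
#'   classical MHC, chr6:28,477,797-33,448,354 (GRCh37).
#' @return `candidates` without the MHC rows; removed rsIDs in
#'   `attr(, "removed")`.
#' @export
exclude_mhc <- function(candidates,
                        region = list(chrom = "6", start = 28477797,
                                      end = 33448354)) {
  inside <- as.character(candidates$chr) == as.character(region$chrom) &
    candidates$pos >= region$start & candidates$pos <= region$end
  out <- candidates[!inside, , drop = FALSE]
  attr(out, "removed") <- candidates$rsid[inside]
  out
}

#' Remove SNVs associated with confounders or the outcome
#'
#' Screens candidates against an offline SNV-to-trait annotation table
#' (standing in for a PhenoScanner query) and against the outcome GWAS:
#' any confounder annotation or outcome association at
#' `p < p_threshold` disqualifies the SNV.
#'
#' @param candidates character vector of rsIDs.
#' @param annotations data frame with columns `rsid`, `trait`, `pval`
#'   (see [read_annotations()]).
#' @param outcome outcome [gwas_table()] (may be `NULL` to skip the
#'   outcome-association rule).
#' @param p_threshold association threshold (default `5e-8`).
#' @return surviving rsIDs; removals with the offending trait in
#'   `attr(, "removed")` (data frame `rsid`, `trait`, `pval`).
#' @export
exclude_pleiotropic <- function(candidates, annotations, outcome = NULL,
                                p_threshold = 5e-8) {
  removed <- data.frame(rsid = character(), trait = character(),
                        pval = numeric(), stringsAsFactors = FALSE)
  if (!is.null(annotations) && nrow(annotations) > 0L) {
    hit <- annotations[annotations$rsid %in% candidates &
                       annotations$pval < p_threshold, , drop = FALSE]
    if (nrow(hit) > 0L)
      removed <- rbind(removed, hit[, c("rsid", "trait", "pval")])
  }
  if (!is.null(outcome)) {
    i <- match(candidates, outcome$rsid)
    hit <- which(!is.na(i) & outcome$pval[i] < p_threshold)
    if (length(hit) > 0L)
      removed <- rbind(removed, data.frame(
        rsid = candidates[hit],
        trait = attr(outcome, "trait") %||% "outcome",
        pval = outcome$pval[i[hit]], stringsAsFactors = FALSE))
  }
  out <- setdiff(candidates, removed$rsid)
  attr(out, "removed") <- removed
  out
}

#' Instrument-strength F statistic
#'
#' `F = (R^2 / k) / ((1 - R^2) / (n - k - 1))` where `R^2` is the variance
#' in the exposure explained by the instrument, `k` the number of SNVs in
#' the instrument and `n` the exposure GWAS sample size.  `F < 10`
#' conventionally flags a weak instrument.
#'
#' @param r2 explained variance, in `[0, 1)`.
#' @param k number of SNVs (per-SNV usage sets `k = 1`).
#' @param n exposure sample size; must exceed `k + 1`.
#' @return the F value.
#' @export
f_statistic <- function(r2, k, n) {
  stopifnot(all(r2 >= 0), all(r2 < 1))
  if (any(n <= k + 1)) stop("n must exceed k + 1")
  (r2 / k) * (n - k - 1) / (1 - r2)
}

#' Per-SNV explained variance for a standardized trait
#'
#' `R^2 = 2 f (1 - f) beta^2` with `f` the effect-allele frequency and
#' `beta` the per-allele effect in SD units; when `f` is missing, the
#' z-statistic approximation `z^2 / (z^2 + n - 2)` is used instead.
#'
#' @param beta per-allele effect (SD units).
#' @param eaf effect-allele frequency (may be `NA`).
#' @param se standard error (used by the fallback).
#' @param n sample size (used by the fallback).
#' @return explained variance per SNV.
#' @export
snp_r2 <- function(beta, eaf, se = NULL, n = NULL) {
  r2 <- 2 * eaf * (1 - eaf) * beta^2
  fallback <- is.na(r2)
  if (any(fallback)) {
    if (is.null(se) || is.null(n))
      stop("se and n are required when eaf is missing")
    z2 <- (beta / se)^2
    r2[fallback] <- (z2 / (z2 + n - 2))[fallback]
  }
  pmin(r2, 1 - 1e-12)
}

#' Design-based power of a two-sample MR study
#'
#' Normal-approximation power for detecting an odds ratio `odds_ratio` per
#' SD of the exposure with instruments explaining `r2_sum` of its
#' variance, in a case-control outcome GWAS of `n_outcome` individuals of
#' which a fraction `case_fraction` are cases:
#' `power = Phi( sqrt(n * r2 * cf * (1 - cf)) * |ln OR| - z_{1 - alpha/2} )`.
#'
#' @param n_outcome total outcome sample size.
#' @param case_fraction cases / total, in (0, 1).
#' @param r2_sum summed instrument explained variance.
#' @param odds_ratio hypothesized OR per SD of exposure.
#' @param alpha two-sided test size (default 0.05).
#' @return data frame echoing the design with the attained `power`.
#' @export
mr_power <- function(n_outcome, case_fraction, r2_sum, odds_ratio,
                     alpha = 0.05) {
  stopifnot(n_outcome > 0, case_fraction > 0, case_fraction < 1,
            r2_sum >= 0, odds_ratio > 0, alpha > 0, alpha < 1)
  ncp <- sqrt(n_outcome * r2_sum * case_fraction * (1 - case_fraction)) *
    abs(log(odds_ratio))
  data.frame(n_outcome = n_outcome, case_fraction = case_fraction,
             r2_sum = r2_sum, odds_ratio = odds_ratio, alpha = alpha,
             power = pnorm(ncp - qnorm(1 - alpha / 2)))
}

#' Read / write a square LD (r-squared) matrix
#'
#' Tab-separated square matrix with an rsID header row and first column;
#' validated to be symmetric with unit diagonal and entries in `[0, 1]`.
#'
#' @param path file path.
#' @return numeric matrix with rsID dimnames.
#' @export
read_ld_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  validate_ld_matrix(m)
}

#' @rdname read_ld_matrix
#' @param ld matrix to write.
#' @export
write_ld_matrix <- function(ld, path) {
  utils::write.table(data.frame(rsid = rownames(ld), ld,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_ld_matrix
#' @export
validate_ld_matrix <- function(ld) {
  if (!isTRUE(all.equal(ld, t(ld), tolerance = 1e-8)))
    stop("LD matrix is not symmetric")
  if (any(abs(diag(ld) - 1) > 1e-8)) stop("LD matrix diagonal must be 1")
  if (any(ld < -1e-12 | ld > 1 + 1e-12)) stop("LD entries must be in [0, 1]")
  if (is.null(rownames(ld))) stop("LD matrix needs rsID dimnames")
  ld
}

#' Read an SNV-to-trait annotation table
#'
#' Tab-separated columns `rsid`, `trait`, `pval`; an offline stand-in for
#' a PhenoScanner confounder lookup.
#'
#' @param path file path.
#' @return data frame with columns `rsid`, `trait`, `pval`.
#' @export
read_annotations <- function(path) {
  a <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("rsid", "trait", "pval") %in% names(a)))
  if (any(!(a$pval > 0 & a$pval <= 1))) stop("annotation pval out of (0, 1]")
  a
}
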