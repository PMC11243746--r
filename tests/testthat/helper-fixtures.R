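# Builders for small in-code fixtures shared across the test files.

# A gwas_table from explicit per-SNV vectors, with defaults that satisfy
# every record invariant.
tiny_table <- function(rsid, beta, se, pval = NULL, ea = "A", oa = "G",
                       eaf = 0.3, chr = "1", pos = NULL, n = 10000,
                       trait = "iron",
                       direction_sign = if (trait == "tibc") -1 else 1) {
  J <- length(rsid)
  if (is.null(pos)) pos <- seq_len(J) * 1000
  if (is.null(pval)) pval <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  gwas_table(data.frame(rsid = rsid, chr = rep_len(chr, J),
                        pos = pos, ea = rep_len(ea, J),
                        oa = rep_len(oa, J), eaf = rep_len(eaf, J),
                        beta = beta, se = se, pval = pval,
                        n = rep_len(n, J), stringsAsFactors = FALSE),
             trait = trait, direction_sign = direction_sign)
}

# A harmonized_set built directly from effect matrices, bypassing
# harmonize(), so estimator tests control their inputs exactly.
make_hset <- function(bx, sx, by, sy, eaf = NULL, nx = NULL, ny = NULL,
                      traits = NULL) {
  bx <- as.matrix(bx); sx <- as.matrix(sx)
  J <- nrow(bx); K <- ncol(bx)
  if (is.null(traits)) traits <- paste0("exp", seq_len(K))
  colnames(bx) <- colnames(sx) <- traits
  rsid <- sprintf("rs%03d", seq_len(J))
  rownames(bx) <- rownames(sx) <- rsid
  if (is.null(eaf)) eaf <- rep(0.3, J)
  if (is.null(nx)) nx <- matrix(10000, J, K, dimnames = list(rsid, traits))
  if (is.null(ny)) ny <- rep(20000, J)
  structure(list(
    rsids = rsid, bx = bx, sx = sx,
    px = matrix(0.5, J, K, dimnames = list(rsid, traits)), nx = nx,
    by = setNames(by, rsid), sy = setNames(sy, rsid),
    ny = setNames(ny, rsid), eaf = setNames(eaf, rsid),
    orientation = setNames(rep("A", J), rsid),
    other_allele = setNames(rep("G", J), rsid),
    chr = setNames(rep("1", J), rsid),
    pos = setNames(seq_len(J) * 1000, rsid),
    direction_signs = rep(1, K), exposure_traits = traits,
    outcome_trait = "outcome",
    dropped = data.frame(rsid = character(), table = character(),
                         reason = character(), stringsAsFactors = FALSE)
  ), class = "harmonized_set")
}

# Rebuild gwas_tables from a harmonized set (all records on the
# harmonized orientation) for idempotence checks.
hset_to_tables <- function(h) {
  base <- function(beta, se, pval, n, trait) {
    gwas_table(data.frame(rsid = h$rsids, chr = h$chr, pos = h$pos,
                          ea = h$orientation, oa = h$other_allele,
                          eaf = h$eaf, beta = beta, se = se, pval = pval,
                          n = n, stringsAsFactors = FALSE, row.names = NULL),
               trait = trait)
  }
  exposures <- lapply(seq_along(h$exposure_traits), function(k)
    base(h$bx[, k], h$sx[, k], h$px[, k], h$nx[, k],
         h$exposure_traits[k]))
  names(exposures) <- h$exposure_traits
  outcome <- base(h$by, h$sy, rep(0.5, length(h$rsids)), h$ny, "outcome")
  list(exposures = exposures, outcome = outcome)
}

# Drop bookkeeping fields so harmonized sets from different but
# equivalent inputs compare equal.
hset_core <- function(h) {
  h$dropped <- NULL
  h
}
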