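.complement <- function(a) chartr("ACGT", "TGCA", a)

.is_palindromic <- function(ea, oa) ea == .complement(oa)

# Align one record onto a reference (ref_ea, ref_oa) orientation.
# Returns list(action = "keep" | "flip" | "drop", reason, strand_flipped).
# For palindromic pairs the allele letters cannot resolve strand, so the
# minor-allele side of the frequencies decides; frequencies near 0.5
# (>= maf_cut) or missing are uninformative and the record is dropped.
.align_alleles <- function(ea, oa, eaf, ref_ea, ref_oa, ref_eaf, maf_cut) {
  pal <- .is_palindromic(ref_ea, ref_oa)
  if (ea == ref_ea && oa == ref_oa) {
    action <- "keep"
  } else if (ea == ref_oa && oa == ref_ea) {
    action <- "flip"
  } else if (!pal && .complement(ea) == ref_ea && .complement(oa) == ref_oa) {
    action <- "keep"
  } else if (!pal && .complement(ea) == ref_oa && .complement(oa) == ref_ea) {
    action <- "flip"
  } else {
    return(list(action = "drop", reason = "allele_mismatch"))
  }
  if (pal) {
    if (is.na(eaf) || is.na(ref_eaf))
      return(list(action = "drop", reason = "missing_eaf_palindromic"))
    if (min(eaf, 1 - eaf) >= maf_cut || min(ref_eaf, 1 - ref_eaf) >= maf_cut)
      return(list(action = "drop", reason = "palindromic_ambiguous"))
    eaf_letter <- if (action == "flip") 1 - eaf else eaf
    if ((eaf_letter < 0.5) != (ref_eaf < 0.5))
      action <- if (action == "keep") "flip" else "keep"
  }
  list(action = action, reason = "")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Puts per-SNV association records from four exposure GWAS and one
#' outcome GWAS onto a single effect-allele orientation (that of the first
#' exposure table), re-signing betas and complementing strand-flipped
#' allele codes as needed.  Palindromic SNVs (A/T or G/C) are aligned by
#' the minor-allele side of the effect-allele frequencies and are dropped
#' when the frequency is missing or uninformative (minor-allele frequency
#' at or above `palindrome_maf_cut` on either side).  SNVs whose allele
#' pair cannot be reconciled by swapping and/or strand complementation are
#' dropped with reason `"allele_mismatch"`.  Nothing is lost silently:
#' every requested rsID ends up either in the harmonized set or in the
#' drop report.
#'
#' @param exposures list of exposure [gwas_table()]s (typically serum
#'   iron, ferritin, transferrin saturation, TIBC).
#' @param outcome outcome [gwas_table()] (log-odds scale).
#' @param palindrome_maf_cut palindromic SNVs are dropped when
#'   `min(eaf, 1 - eaf) >= palindrome_maf_cut` on either side
#'   (default 0.42).
#' @param snps optional character vector of rsIDs to harmonize; defaults
#'   to all rsIDs seen in any table (those absent from some table are
#'   reported as dropped with reason `"absent"`).
#' @return object of class `harmonized_set`: list with `rsids`,
#'   `bx`/`sx`/`px`/`nx` (J x K exposure matrices), `by`/`sy`/`ny`
#'   (outcome vectors), `eaf` (effect-allele frequency on the harmonized
#'   orientation), `orientation` (effect allele per rsID), `chr`, `pos`,
#'   `direction_signs`, and `dropped` (data frame of `rsid`, `table`,
#'   `reason`).
#' @export
harmonize <- function(exposures, outcome, palindrome_maf_cut = 0.42,
                      snps = NULL) {
  stopifnot(is.list(exposures), length(exposures) >= 1L)
  tables <- c(exposures, list(outcome))
  labels <- vapply(tables, function(t) attr(t, "trait") %||% "trait",
                   character(1))
  labels <- make.unique(labels)
  K <- length(exposures)
  if (is.null(snps))
    snps <- unique(unlist(lapply(tables, function(t) t$rsid)))
  snps <- unique(as.character(snps))

  idx <- lapply(tables, function(t) match(snps, t$rsid))
  present <- Reduce(`&`, lapply(idx, function(i) !is.na(i)))
  dropped <- data.frame(rsid = character(), table = character(),
                        reason = character(), stringsAsFactors = FALSE)
  if (any(!present)) {
    miss_tab <- vapply(which(!present), function(j) {
      labels[which(vapply(idx, function(i) is.na(i[j]), logical(1)))[1]]
    }, character(1))
    dropped <- rbind(dropped, data.frame(rsid = snps[!present],
                                         table = miss_tab,
                                         reason = "absent",
                                         stringsAsFactors = FALSE))
  }
  keep_snps <- snps[present]
  J <- length(keep_snps)
  ref <- as.data.frame(tables[[1]])[idx[[1]][present], , drop = FALSE]

  bx <- sx <- px <- nx <- matrix(NA_real_, J, K,
                                 dimnames = list(keep_snps, labels[seq_len(K)]))
  by <- sy <- ny <- setNames(rep(NA_real_, J), keep_snps)
  ok <- rep(TRUE, J)

  for (t in seq_along(tables)) {
    tab <- as.data.frame(tables[[t]])[match(keep_snps, tables[[t]]$rsid), ,
                                      drop = FALSE]
    for (j in seq_len(J)) {
      if (!ok[j]) next
      al <- .align_alleles(tab$ea[j], tab$oa[j], tab$eaf[j],
                           ref$ea[j], ref$oa[j], ref$eaf[j],
                           palindrome_maf_cut)
      if (al$action == "drop") {
        ok[j] <- FALSE
        dropped <- rbind(dropped,
                         data.frame(rsid = keep_snps[j], table = labels[t],
                                    reason = al$reason,
                                    stringsAsFactors = FALSE))
        next
      }
      b <- if (al$action == "flip") -tab$beta[j] else tab$beta[j]
      if (t <= K) {
        bx[j, t] <- b; sx[j, t] <- tab$se[j]
        px[j, t] <- tab$pval[j]; nx[j, t] <- tab$n[j]
      } else {
        by[j] <- b; sy[j] <- tab$se[j]; ny[j] <- tab$n[j]
      }
    }
  }

  sel <- which(ok)
  structure(list(
    rsids = keep_snps[sel],
    bx = bx[sel, , drop = FALSE],
    sx = sx[sel, , drop = FALSE],
    px = px[sel, , drop = FALSE],
    nx = nx[sel, , drop = FALSE],
    by = by[sel],
    sy = sy[sel],
    ny = ny[sel],
    eaf = setNames(ref$eaf[sel], keep_snps[sel]),
    orientation = setNames(ref$ea[sel], keep_snps[sel]),
    other_allele = setNames(ref$oa[sel], keep_snps[sel]),
    chr = setNames(ref$chr[sel], keep_snps[sel]),
    pos = setNames(ref$pos[sel], keep_snps[sel]),
    direction_signs = vapply(exposures, function(e)
      attr(e, "direction_sign") %||% 1, numeric(1)),
    exposure_traits = labels[seq_len(K)],
    outcome_trait = labels[K + 1L],
    dropped = dropped
  ), class = "harmonized_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized instrument set: %d SNVs x %d exposures -> '%s'\n",
              length(x$rsids), ncol(x$bx), x$outcome_trait))
  cat("  exposures:", paste(x$exposure_traits, collapse = ", "), "\n")
  if (nrow(x$dropped) > 0L) {
    tab <- table(x$dropped$reason)
    cat("  dropped:", paste(sprintf("%s (%d)", names(tab), tab),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a harmonized set to selected instruments
#'
#' @param x a [harmonize()]d set.
#' @param rsids rsIDs (or integer indices) to keep, in the given order.
#' @return a `harmonized_set` restricted to `rsids`.
#' @export
subset_harmonized <- function(x, rsids) {
  i <- if (is.character(rsids)) match(rsids, x$rsids) else as.integer(rsids)
  if (anyNA(i)) stop("rsid(s) not in harmonized set: ",
                     paste(rsids[is.na(i)], collapse = ", "))
  x$rsids <- x$rsids[i]
  for (f in c("by", "sy", "ny", "eaf", "orientation", "other_allele",
              "chr", "pos"))
    x[[f]] <- x[[f]][i]
  for (f in c("bx", "sx", "px", "nx"))
    x[[f]] <- x[[f]][i, , drop = FALSE]
  x
}
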