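# Required column dialect for GWAS summary-statistic tables.
.SUMSTAT_COLS <- c("rsid", "chr", "pos", "ea", "oa", "eaf", "beta", "se",
                   "pval", "n")

.VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a GWAS summary-statistic table
#'
#' A `gwas_table` is a validated data frame of per-SNV association records
#' for one trait: rsID, chromosome, 1-based position (GRCh37), effect and
#' other allele, effect-allele frequency (may be `NA`), additive effect per
#' effect allele (SD units for continuous biomarkers, log-odds for a binary
#' outcome), its standard error, p-value and sample size.
#'
#' `direction_sign` encodes how the biomarker tracks systemic iron status:
#' +1 for serum iron, ferritin and transferrin saturation, -1 for total
#' iron-binding capacity, which rises when iron status falls.
#'
#' @param x data frame with columns `rsid`, `chr`, `pos`, `ea`, `oa`,
#'   `eaf`, `beta`, `se`, `pval`, `n`.
#' @param trait trait label, e.g. `"iron"`, `"ferritin"`, `"tfsat"`,
#'   `"tibc"` or `"outcome"`.
#' @param direction_sign +1 or -1; defaults to -1 when `trait == "tibc"`,
#'   +1 otherwise.
#' @return object of class `gwas_table` (a data frame with `trait` and
#'   `direction_sign` attributes).
#' @export
gwas_table <- function(x, trait,
                       direction_sign = if (identical(trait, "tibc")) -1 else 1) {
  stopifnot(is.data.frame(x), direction_sign %in% c(-1, 1))
  missing_cols <- setdiff(.SUMSTAT_COLS, names(x))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  x <- as.data.frame(x)[, .SUMSTAT_COLS]
  x$rsid <- as.character(x$rsid)
  x$chr <- as.character(x$chr)
  x$ea <- toupper(as.character(x$ea))
  x$oa <- toupper(as.character(x$oa))
  dup <- x$rsid[duplicated(x$rsid)]
  if (length(dup) > 0L)
    stop("duplicate rsid(s): ", paste(unique(dup), collapse = ", "))
  bad <- .invalid_rows(x)
  if (any(bad != ""))
    stop("invalid record(s): ",
         paste(sprintf("%s (%s)", x$rsid[bad != ""], bad[bad != ""]),
               collapse = "; "))
  rownames(x) <- NULL
  structure(x, trait = trait, direction_sign = direction_sign,
            class = c("gwas_table", "data.frame"))
}

# One reason string per row; "" when the row satisfies all invariants.
.invalid_rows <- function(x) {
  reason <- character(nrow(x))
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- TRUE
    reason[reason == "" & cond] <<- msg
  }
  flag(!(x$ea %in% .VALID_ALLELES) | !(x$oa %in% .VALID_ALLELES),
       "invalid_allele")
  flag(x$ea == x$oa, "ea_equals_oa")
  flag(!(x$se > 0), "nonpositive_se")
  flag(!(x$pval > 0 & x$pval <= 1), "pval_out_of_range")
  flag(!(x$n > 0), "nonpositive_n")
  flag(!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1), "eaf_out_of_range")
  flag(!(x$pos > 0), "nonpositive_pos")
  reason
}

#' Read a GWAS summary-statistic table
#'
#' Reads a tab-separated table with header columns `rsid`, `chr`, `pos`,
#' `ea`, `oa`, `eaf`, `beta`, `se`, `pval`, `n` (`.` marks a missing
#' effect-allele frequency).  Rows violating the record invariants
#' (alleles in A/C/G/T and distinct, `se > 0`, `pval` in (0, 1],
#' `eaf` in [0, 1] when present, positive `n` and position) are rejected;
#' the per-row report is attached as attribute `"rejected"`.
#'
#' @param path file path.
#' @param trait trait label stored on the returned table.
#' @param direction_sign see [gwas_table()].
#' @return a [gwas_table()]; rejected rows (if any) in
#'   `attr(, "rejected")` as a data frame of `rsid`, `row`, `reason`.
#' @export
read_sumstats <- function(path, trait,
                          direction_sign = if (identical(trait, "tibc")) -1 else 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = ".",
                           check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.SUMSTAT_COLS, names(raw))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  raw <- raw[, .SUMSTAT_COLS]
  for (col in c("pos", "eaf", "beta", "se", "pval", "n"))
    raw[[col]] <- as.numeric(raw[[col]])
  raw$ea <- toupper(raw$ea)
  raw$oa <- toupper(raw$oa)
  dup <- unique(raw$rsid[duplicated(raw$rsid)])
  if (length(dup) > 0L)
    stop("duplicate rsid(s): ", paste(dup, collapse = ", "))
  reason <- .invalid_rows(raw)
  rejected <- data.frame(rsid = raw$rsid[reason != ""],
                         row = which(reason != ""),
                         reason = reason[reason != ""],
                         stringsAsFactors = FALSE)
  out <- gwas_table(raw[reason == "", , drop = FALSE], trait = trait,
                    direction_sign = direction_sign)
  attr(out, "rejected") <- rejected
  out
}

#' Write a GWAS summary-statistic table
#'
#' Inverse of [read_sumstats()]: tab-separated, `.` for missing
#' effect-allele frequency.
#'
#' @param x a [gwas_table()] or compatible data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  out <- as.data.frame(x)[, .SUMSTAT_COLS]
  out$eaf <- ifelse(is.na(out$eaf), ".", format(out$eaf, digits = 15,
                                                scientific = FALSE,
                                                trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.gwas_table <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: trait '%s' (direction sign %+d), %d SNVs\n",
              attr(x, "trait"), attr(x, "direction_sign"), nrow(x)))
  rej <- attr(x, "rejected")
  if (!is.null(rej) && nrow(rej) > 0L)
    cat(sprintf("  %d input row(s) rejected at read time\n", nrow(rej)))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
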