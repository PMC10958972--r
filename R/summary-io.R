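#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated file with columns SNP, CHR, POS, A1 (effect allele),
#' A2, and any of BETA / OR, SE, Z, P, N. An OR column is converted to
#' `BETA = log(OR)`; missing Z is reconstructed as BETA/SE and missing P as
#' the two-sided normal tail of Z. The result is validated with
#' [validate_sumstats()].
#'
#' @param path Path to a TSV file with a header row.
#' @return A validated summary-statistics data.frame.
#' @export
read_sumstats <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(df[["OR"]]) && is.null(df[["BETA"]])) df$BETA <- log(df[["OR"]])
  if (is.null(df[["Z"]]) && !is.null(df[["BETA"]]) && !is.null(df[["SE"]]))
    df$Z <- df[["BETA"]] / df[["SE"]]
  if (is.null(df[["P"]]) && !is.null(df[["Z"]])) df$P <- .z2p(df[["Z"]])
  validate_sumstats(df)
}

#' Write a summary-statistics table
#' @param sumstats A summary-statistics data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(sumstats, path) {
  utils::write.table(sumstats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a summary-statistics table
#'
#' Checks the column contract: required columns present, SE > 0, P in (0, 1],
#' alleles single A/C/G/T characters, and Z consistent with BETA/SE to 1e-6
#' where both are present. Rows violating per-record rules are dropped with a
#' warning; structural problems are errors.
#'
#' @param sumstats A data.frame of summary statistics.
#' @return The validated (possibly row-filtered) data.frame.
#' @export
validate_sumstats <- function(sumstats) {
  need <- c("SNP", "CHR", "POS", "A1", "A2", "BETA", "SE", "Z", "P", "N")
  miss <- setdiff(need, names(sumstats))
  if (length(miss)) .stopf("sumstats missing columns: %s", paste(miss, collapse = ", "))
  ok <- rep(TRUE, nrow(sumstats))
  ok <- ok & sumstats$SE > 0 & is.finite(sumstats$SE)
  ok <- ok & sumstats$P > 0 & sumstats$P <= 1
  ok <- ok & sumstats$A1 %in% c("A", "C", "G", "T") &
    sumstats$A2 %in% c("A", "C", "G", "T")
  incons <- abs(sumstats$Z - sumstats$BETA / sumstats$SE) > 1e-6
  ok <- ok & !(is.finite(incons) & incons)
  if (any(!ok)) {
    .warnf("dropping %d invalid summary-statistic record(s)", sum(!ok))
    sumstats <- sumstats[ok, , drop = FALSE]
  }
  if (anyDuplicated(sumstats$SNP))
    .stopf("duplicate variant ids in summary statistics")
  rownames(sumstats) <- NULL
  sumstats
}

.palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize summary statistics to a reference allele orientation
#'
#' Aligns each GWAS record to the effect/other allele orientation of a
#' reference variant table (typically the union of prediction-model variants
#' or the LD panel map). Records whose alleles are swapped relative to the
#' reference get Z and BETA negated (`sign_flipped`); strand-ambiguous
#' palindromic SNPs (A/T, C/G) are dropped (`dropped_ambiguous`); allele
#' sets matching neither orientation are dropped (`dropped_mismatch`).
#' Matching is by variant id, falling back to (CHR, POS).
#'
#' @param sumstats A summary-statistics data.frame.
#' @param reference A data.frame with columns SNP, A1, A2 (and optionally
#'   CHR, POS for positional fallback).
#' @return An object of class `harmonized_set`: list with `records` (all
#'   matched records, reference orientation where kept, plus a `flag`
#'   column) and `z` (named z-score vector over kept records).
#' @export
harmonize <- function(sumstats, reference) {
  if (anyDuplicated(reference$SNP)) {
    reference <- reference[!duplicated(reference$SNP), , drop = FALSE]
  }
  mi <- match(sumstats$SNP, reference$SNP)
  if (anyNA(mi) && all(c("CHR", "POS") %in% names(reference))) {
    key_s <- paste(sumstats$CHR, sumstats$POS)
    key_r <- paste(reference$CHR, reference$POS)
    mi2 <- match(key_s, key_r)
    mi[is.na(mi)] <- mi2[is.na(mi)]
  }
  hit <- !is.na(mi)
  rec <- sumstats[hit, , drop = FALSE]
  ref <- reference[mi[hit], , drop = FALSE]

  flag <- rep("dropped_mismatch", nrow(rec))
  same <- rec$A1 == ref$A1 & rec$A2 == ref$A2
  swap <- rec$A1 == ref$A2 & rec$A2 == ref$A1
  ambi <- .palindromic(rec$A1, rec$A2)
  flag[same] <- "kept"
  flag[swap & !same] <- "sign_flipped"
  flag[ambi] <- "dropped_ambiguous"

  fl <- flag == "sign_flipped"
  rec$Z[fl] <- -rec$Z[fl]
  rec$BETA[fl] <- -rec$BETA[fl]
  rec$A1[fl | same] <- ref$A1[fl | same]
  rec$A2[fl | same] <- ref$A2[fl | same]
  rec$flag <- flag
  if (anyDuplicated(rec$SNP)) rec <- rec[!duplicated(rec$SNP), , drop = FALSE]
  rownames(rec) <- NULL
  keep <- rec$flag %in% c("kept", "sign_flipped")
  structure(list(records = rec,
                 z = stats::setNames(rec$Z[keep], rec$SNP[keep])),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  tab <- table(x$records$flag)
  cat("Harmonized summary statistics:\n")
  for (f in names(tab)) cat(sprintf("  %-18s %d\n", f, tab[[f]]))
  invisible(x)
}

#' Inverse-variance fixed-effects meta-analysis of two studies
#'
#' Combines two harmonized summary-statistic tables per shared variant with
#' inverse-variance weights:
#' `beta = (sum beta_i / SE_i^2) / (sum 1 / SE_i^2)`,
#' `SE = (sum 1 / SE_i^2)^{-1/2}`; Z and P are recomputed from the combined
#' estimate and N is summed. Variants present in only one study carry that
#' study's values and are flagged `single_study`.
#'
#' @param s1,s2 Summary-statistics data.frames on a shared allele
#'   orientation.
#' @return A summary-statistics data.frame with a `meta` flag column
#'   (`combined` or `single_study`).
#' @export
meta_fixed_effects <- function(s1, s2) {
  bad1 <- s1$SE <= 0; bad2 <- s2$SE <= 0
  if (any(bad1)) s1 <- s1[!bad1, , drop = FALSE]
  if (any(bad2)) s2 <- s2[!bad2, , drop = FALSE]
  if (any(bad1) || any(bad2))
    .warnf("rejected %d record(s) with non-positive SE", sum(bad1) + sum(bad2))

  shared <- intersect(s1$SNP, s2$SNP)
  a <- s1[match(shared, s1$SNP), , drop = FALSE]
  b <- s2[match(shared, s2$SNP), , drop = FALSE]
  flip <- a$A1 == b$A2 & a$A2 == b$A1
  b$BETA[flip] <- -b$BETA[flip]
  mismatch <- !(a$A1 == b$A1 & a$A2 == b$A2) & !flip
  if (any(mismatch)) {
    .warnf("dropping %d shared variant(s) with irreconcilable alleles", sum(mismatch))
    a <- a[!mismatch, , drop = FALSE]; b <- b[!mismatch, , drop = FALSE]
  }
  w1 <- 1 / a$SE^2; w2 <- 1 / b$SE^2
  beta <- (a$BETA * w1 + b$BETA * w2) / (w1 + w2)
  se <- 1 / sqrt(w1 + w2)
  comb <- data.frame(
    SNP = a$SNP, CHR = a$CHR, POS = a$POS, A1 = a$A1, A2 = a$A2,
    BETA = beta, SE = se, Z = beta / se, P = .z2p(beta / se),
    N = a$N + b$N, meta = rep("combined", nrow(a)), stringsAsFactors = FALSE
  )
  only <- rbind(s1[!s1$SNP %in% shared, , drop = FALSE],
                s2[!s2$SNP %in% shared, , drop = FALSE])
  if (nrow(only)) {
    only <- only[, c("SNP", "CHR", "POS", "A1", "A2", "BETA", "SE", "Z", "P", "N")]
    only$meta <- "single_study"
    comb <- rbind(comb, only)
  }
  comb <- comb[order(comb$CHR, comb$POS, comb$SNP), , drop = FALSE]
  rownames(comb) <- NULL
  comb
}
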