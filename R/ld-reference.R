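#' Build an LD block from a genotype dosage panel
#'
#' Computes the sample covariance `Gamma` and correlation `R` of the dosages
#' over a variant subset, with optional ridge regularization of the
#' correlation: `R <- (1 - ridge) * R + ridge * I`, which bounds its
#' smallest eigenvalue below by `ridge` times a positive constant.
#' Monomorphic SNPs are dropped with a warning.
#'
#' @param panel A `geno_panel`, or any n x m dosage matrix with column
#'   names; if a matrix, `map` must be supplied.
#' @param variants Character vector of SNP ids to include (default: all).
#' @param ridge Ridge weight in `[0, 1]` applied to `R` (0 keeps the
#'   unbiased sample correlation; the imputation convention is 0.1).
#' @param map Variant metadata data.frame (SNP, CHR, POS, A1, A2) when
#'   `panel` is a bare matrix.
#' @return An object of class `ld_block`: list with `snps` (metadata),
#'   `sigma` (per-SNP dosage SD), `Gamma`, `R` and `ridge`.
#' @export
build_ld <- function(panel, variants = NULL, ridge = 0, map = NULL) {
  if (inherits(panel, "geno_panel")) {
    dosage <- panel$dosage
    map <- panel$map
  } else {
    dosage <- panel
    if (is.null(map)) .stopf("map is required when panel is a bare matrix")
  }
  if (nrow(dosage) < 2) .stopf("need at least 2 individuals")
  if (is.null(variants)) variants <- colnames(dosage)
  if (length(variants) == 0) .stopf("empty variant subset")
  missing <- setdiff(variants, colnames(dosage))
  if (length(missing)) .stopf("variants absent from panel: %s",
                              paste(utils::head(missing, 5), collapse = ", "))
  X <- dosage[, variants, drop = FALSE]
  sigma <- apply(X, 2, stats::sd)
  mono <- sigma == 0
  if (any(mono)) {
    .warnf("dropping %d monomorphic SNP(s)", sum(mono))
    X <- X[, !mono, drop = FALSE]
    variants <- variants[!mono]
    sigma <- sigma[!mono]
  }
  if (ncol(X) == 0) .stopf("no polymorphic SNPs left in subset")
  Gamma <- stats::cov(X)
  R <- Gamma / outer(sigma, sigma)
  if (ridge < 0 || ridge > 1) .stopf("ridge must be in [0, 1]")
  if (ridge > 0) R <- (1 - ridge) * R + diag(ridge, ncol(R))
  snps <- map[match(variants, map$SNP), , drop = FALSE]
  rownames(snps) <- NULL
  structure(list(snps = snps, sigma = sigma, Gamma = Gamma, R = R,
                 ridge = ridge), class = "ld_block")
}

#' @export
print.ld_block <- function(x, ...) {
  cat(sprintf("LD block: %d SNPs (ridge = %g)\n", length(x$sigma), x$ridge))
  invisible(x)
}

#' Write an LD block to a matrix file plus variant sidecar
#'
#' Writes `<prefix>.ld.tsv` (the covariance matrix `Gamma`) and
#' `<prefix>.vars.tsv` (SNP, CHR, POS, A1, A2, SD).
#'
#' @param ld An `ld_block`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_ld <- function(ld, prefix) {
  G <- as.data.frame(ld$Gamma)
  names(G) <- ld$snps$SNP
  utils::write.table(G, paste0(prefix, ".ld.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- ld$snps[, c("SNP", "CHR", "POS", "A1", "A2"), drop = FALSE]
  side$SD <- ld$sigma
  utils::write.table(side, paste0(prefix, ".vars.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read an LD block written by [write_ld()]
#' @param prefix Path prefix used at write time.
#' @param ridge Ridge weight applied to the reconstructed correlation.
#' @return An `ld_block`.
#' @export
read_ld <- function(prefix, ridge = 0) {
  G <- as.matrix(utils::read.delim(paste0(prefix, ".ld.tsv"),
                                   check.names = FALSE))
  side <- utils::read.delim(paste0(prefix, ".vars.tsv"), stringsAsFactors = FALSE)
  sigma <- side$SD
  dimnames(G) <- list(side$SNP, side$SNP)
  R <- G / outer(sigma, sigma)
  if (ridge > 0) R <- (1 - ridge) * R + diag(ridge, ncol(R))
  snps <- side[, c("SNP", "CHR", "POS", "A1", "A2"), drop = FALSE]
  structure(list(snps = snps, sigma = stats::setNames(sigma, side$SNP),
                 Gamma = G, R = R, ridge = ridge), class = "ld_block")
}

# Index a set of SNP ids into an ld_block, erroring on absences.
.ld_index <- function(ld, snps) {
  idx <- match(snps, ld$snps$SNP)
  if (anyNA(idx)) .stopf("SNP(s) absent from LD block: %s",
                         paste(utils::head(snps[is.na(idx)], 5), collapse = ", "))
  idx
}
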