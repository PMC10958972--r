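# Small in-code fixtures shared across test files.

# An ld_block with exactly known covariance, bypassing sampling noise.
exact_ld <- function(R, sigma = rep(1, nrow(R)), snps = NULL) {
  m <- nrow(R)
  if (is.null(snps)) snps <- sprintf("s%d", seq_len(m))
  Gamma <- R * outer(sigma, sigma)
  dimnames(R) <- dimnames(Gamma) <- list(snps, snps)
  structure(list(
    snps = data.frame(SNP = snps, CHR = 1L, POS = seq_len(m) * 1000L,
                      A1 = "A", A2 = "G", stringsAsFactors = FALSE),
    sigma = stats::setNames(sigma, snps), Gamma = Gamma, R = R, ridge = 0),
    class = "ld_block")
}

# Minimal sumstats row constructor.
sumstat_row <- function(snp, a1, a2, z, se = 0.1, chr = 1L, pos = 1000L,
                        n = 1000L) {
  data.frame(SNP = snp, CHR = chr, POS = pos, A1 = a1, A2 = a2,
             BETA = z * se, SE = se, Z = z, P = 2 * pnorm(-abs(z)), N = n,
             stringsAsFactors = FALSE)
}

# One-feature weight model data.frame in registry row format.
weight_model <- function(feature_id, snps, weights, tissue = "breast",
                         feature_type = "gene", gene_id = feature_id,
                         a1 = "A", a2 = "G") {
  data.frame(feature_id = feature_id, feature_type = feature_type,
             gene_id = gene_id, tissue = tissue, SNP = snps, A1 = a1,
             A2 = a2, weight = weights, stringsAsFactors = FALSE)
}
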