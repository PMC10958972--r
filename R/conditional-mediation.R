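#' Condition z-scores on GWAS index variants
#'
#' Residualizes target z-scores on a set of index-variant z-scores using the
#' LD correlation structure (summary-statistic conditional analysis):
#' `z_adj_j = (z_j - R_jI R_II^{-1} z_I) / sqrt(1 - R_jI R_II^{-1} R_Ij)`.
#' Index variants are LD-pruned at `r^2 > 0.9` before conditioning to keep
#' `R_II` well-conditioned, and a small ridge is added before inversion.
#' Targets collinear with the index set (denominator at or below the floor)
#' get `z_adj = 0` with a `collinear` flag; an empty index set is the
#' identity map.
#'
#' @param z Named vector of target z-scores (names are SNP ids in `ld`).
#' @param index_snps Character vector of index-variant ids; their z-scores
#'   are taken from `z_index` or, if `NULL`, from `z`.
#' @param ld An `ld_block` covering targets and index variants.
#' @param z_index Optional named z-score vector for the index variants.
#' @param ridge Ridge added to `R_II` before inversion (default 1e-6).
#' @param floor Collinearity floor on the conditional variance
#'   `1 - R_jI R_II^{-1} R_Ij` (default 1e-4).
#' @return A data.frame with SNP, Z (input), Z_ADJ and COLLINEAR flag.
#' @export
conditional_z <- function(z, index_snps, ld, z_index = NULL,
                          ridge = 1e-6, floor = 1e-4) {
  out <- data.frame(SNP = names(z), Z = unname(z), Z_ADJ = unname(z),
                    COLLINEAR = FALSE, stringsAsFactors = FALSE)
  if (!length(index_snps)) return(out)
  if (is.null(z_index)) {
    zi <- z[match(index_snps, names(z))]
    if (anyNA(zi)) .stopf("index z-scores not found in z; supply z_index")
  } else {
    zi <- z_index[match(index_snps, names(z_index))]
    if (anyNA(zi)) .stopf("index variant(s) missing from z_index")
  }
  ii <- .ld_index(ld, index_snps)
  # prune near-duplicate index variants (r^2 > 0.9), keeping the first
  keep <- rep(TRUE, length(ii))
  if (length(ii) > 1) {
    Rii <- ld$R[ii, ii, drop = FALSE]
    for (j in 2:length(ii))
      if (any(Rii[j, seq_len(j - 1)][keep[seq_len(j - 1)]]^2 > 0.9)) keep[j] <- FALSE
  }
  ii <- ii[keep]; zi <- zi[keep]

  ti <- .ld_index(ld, names(z))
  Rii <- ld$R[ii, ii, drop = FALSE] + diag(ridge, length(ii))
  Rti <- ld$R[ti, ii, drop = FALSE]
  A <- t(solve(Rii, t(Rti)))            # R_tI R_II^{-1}
  num <- unname(z) - drop(A %*% zi)
  cvar <- 1 - rowSums(A * Rti)
  coll <- cvar <= floor
  zadj <- ifelse(coll, 0, num / sqrt(pmax(cvar, floor)))
  out$Z_ADJ <- zadj
  out$COLLINEAR <- coll
  out
}

# Indices of index SNPs lying within +/- window of a feature's model-SNP span.
.nearby_index <- function(index_df, feat_chr, feat_lo, feat_hi, window) {
  which(index_df$CHR == feat_chr &
        index_df$POS >= feat_lo - window & index_df$POS <= feat_hi + window)
}

#' Re-run the TWAS with model-SNP z-scores conditioned on index variants
#'
#' Forward-direction conditional analysis: for each feature, the z-scores of
#' its model SNPs are residualized on all GWAS index variants within
#' `window` of the feature's span (model weights are untouched), then the
#' TWAS statistic and the two-step ACAT aggregation are recomputed
#' unchanged. Features with no nearby index variant pass through
#' unconditioned and are flagged.
#'
#' @param model_set A `model_set`.
#' @param z Named z-score vector covering model SNPs and index variants.
#' @param index_snps Data.frame with SNP, CHR, POS (e.g. the index-SNP list
#'   of a fixture bundle).
#' @param ld_blocks Named list of `ld_block`s keyed by region id, or one
#'   `ld_block`.
#' @param region_of Named character vector feature_id -> region id (as in
#'   [run_tissue_twas()]).
#' @param window Flanking distance in bp (default 2e6, i.e. +/- 2 Mb).
#' @return List with `results` (per feature x tissue conditioned TWAS
#'   table, plus a CONDITIONED flag) and `genes` (conditioned gene-level
#'   joint p-values per approach).
#' @export
conditional_twas <- function(model_set, z, index_snps, ld_blocks,
                             region_of = NULL, window = 2e6) {
  single <- inherits(ld_blocks, "ld_block")
  rows <- vector("list", length(model_set$models))
  for (i in seq_along(model_set$models)) {
    d <- model_set$models[[i]]
    fid <- d$feature_id[1]
    ld <- if (single) ld_blocks else ld_blocks[[region_of[[fid]]]]
    pos <- ld$snps$POS[.ld_index(ld, d$SNP)]
    nearby <- .nearby_index(index_snps, ld$snps$CHR[1], min(pos), max(pos), window)
    idx_in_ld <- index_snps$SNP[nearby]
    idx_in_ld <- idx_in_ld[idx_in_ld %in% ld$snps$SNP]
    zz <- z[match(d$SNP, names(z))]
    names(zz) <- d$SNP
    conditioned <- FALSE
    if (length(idx_in_ld) && all(is.finite(zz))) {
      adj <- conditional_z(zz, idx_in_ld, ld,
                           z_index = z[match(idx_in_ld, names(z))])
      zz <- stats::setNames(adj$Z_ADJ, adj$SNP)
      conditioned <- TRUE
    }
    st <- .twas_zscore_fast(d$SNP, d$weight, zz, ld)
    rows[[i]] <- data.frame(
      feature_id = fid, feature_type = d$feature_type[1],
      gene_id = d$gene_id[1], tissue = d$tissue[1], Z = st$z, P = st$p,
      NSNP_MODEL = st$n_model, NSNP_USED = st$n_used, SIGMA_G = st$sigma_g,
      FLAGS = st$flag, CONDITIONED = conditioned, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$feature_id, res$tissue), , drop = FALSE]
  rownames(res) <- NULL
  genes <- aggregate_gene_pvalues(res, model_set)
  list(results = res, genes = genes)
}

#' Two-step gene-level aggregation of per-tissue TWAS results
#'
#' Applies the two-step ACAT scheme to a per-(feature, tissue) TWAS table:
#' expression approach - ACAT over tissues of each gene's expression
#' p-values; splicing approach - ACAT over each gene's introns within a
#' tissue, then ACAT over tissues. Untestable (NA) entries are excluded
#' from the weighting (K counts only testable tissues).
#'
#' @param results A TWAS results table ([run_tissue_twas()] rows, any
#'   number of tissues).
#' @param model_set The `model_set` (for the intron -> gene map).
#' @param weight_mode `"equal"` or `"sqrt_n"` tissue weighting.
#' @param tissue_n Optional per-tissue sample sizes for `"sqrt_n"`.
#' @return Data.frame: GENE, APPROACH, JOINT_P, N_TISSUES, BREAST_P,
#'   MIN_TISSUE.
#' @export
aggregate_gene_pvalues <- function(results, model_set,
                                   weight_mode = c("equal", "sqrt_n"),
                                   tissue_n = NULL) {
  weight_mode <- match.arg(weight_mode)
  empty <- data.frame(GENE = character(0), APPROACH = character(0),
                      JOINT_P = numeric(0), N_TISSUES = integer(0),
                      BREAST_P = numeric(0), MIN_TISSUE = character(0))
  # one pass per approach, accumulating plain vectors (a data.frame per
  # gene is prohibitive at genome scale)
  combine <- function(p_by_gene, approach) {
    genes <- names(p_by_gene)
    n <- length(genes)
    if (!n) return(empty)
    jp <- numeric(n); nt <- integer(n); bp <- rep(NA_real_, n)
    mt <- character(n); keep <- rep(TRUE, n)
    for (i in seq_len(n)) {
      tp <- p_by_gene[[i]]
      tp <- tp[is.finite(tp)]
      if (!length(tp)) { keep[i] <- FALSE; next }
      w <- if (weight_mode == "sqrt_n") sqrt(tissue_n[names(tp)]) else NULL
      jp[i] <- acat_pvalue(tp, w)
      nt[i] <- length(tp)
      if ("breast" %in% names(tp)) bp[i] <- unname(tp["breast"])
      mt[i] <- names(tp)[which.min(tp)]
    }
    data.frame(GENE = genes, APPROACH = approach, JOINT_P = jp,
               N_TISSUES = nt, BREAST_P = bp, MIN_TISSUE = mt,
               stringsAsFactors = FALSE)[keep, , drop = FALSE]
  }
  expr <- results[results$feature_type == "gene", , drop = FALSE]
  p_expr <- lapply(split(seq_len(nrow(expr)), expr$gene_id), function(i)
    stats::setNames(ifelse(expr$FLAGS[i] == "untestable", NA_real_, expr$P[i]),
                    expr$tissue[i]))
  spl <- results[results$feature_type == "intron", , drop = FALSE]
  p_spl <- lapply(split(seq_len(nrow(spl)), spl$gene_id), function(i) {
    tis <- unique(spl$tissue[i])
    vapply(tis, function(t)
      splice_gene_pvalue(spl[i[spl$tissue[i] == t], , drop = FALSE]),
      numeric(1), USE.NAMES = TRUE)
  })
  res <- rbind(combine(p_expr, "expression"), combine(p_spl, "splicing"))
  if (!nrow(res)) return(empty)
  res <- res[order(res$APPROACH, res$GENE), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Proportion-mediated arithmetic on the odds-ratio scale
#'
#' `PM = direct * (indirect - 1) / (total - 1)` with
#' `indirect = total / direct`. Equals 1 when the direct (adjusted) effect
#' is null and 0 when adjustment changes nothing.
#'
#' @param total_or,direct_or Total (unadjusted) and direct (adjusted) odds
#'   ratios; `total_or` must differ from 1.
#' @return The proportion mediated.
#' @examples
#' pm_formula(1.2, 1.1)  # 0.5
#' @export
pm_formula <- function(total_or, direct_or) {
  if (any(abs(total_or - 1) < 1e-6)) .stopf("PM undefined at total OR = 1")
  indirect <- total_or / direct_or
  direct_or * (indirect - 1) / (total_or - 1)
}

#' Proportion mediated for a GWAS index variant
#'
#' Reverse-direction analysis: the index variant's z-score is conditioned on
#' the model SNPs (eQTL/sQTL) of the locus; the adjusted (direct) log
#' odds-ratio is reconstructed as `beta_direct = z_adj * SE_total` (the SE
#' is taken as unchanged under the standardized-genotype approximation),
#' the indirect odds ratio is `total OR / direct OR`, and the proportion
#' mediated is `PM = direct * (indirect - 1) / (total - 1)` on the OR
#' scale. The variant is classified mediated when `PM > 0.5` and the
#' adjusted p-value exceeds 5e-8 (no longer genome-wide significant).
#'
#' @param index_record One-row data.frame (or list) with SNP, BETA, SE, Z
#'   for the index variant (total effect).
#' @param model_snps Character vector of adjusting model-SNP ids (nonempty).
#' @param ld An `ld_block` covering the index variant and model SNPs.
#' @param z Named z-score vector supplying the model SNPs' z-scores.
#' @param per_gene Optional named list gene -> SNP ids; when supplied, a
#'   per-gene PM is computed against each gene's own model SNPs in addition
#'   to the joint record (joint adjustment over all locus model SNPs is the
#'   primary definition).
#' @return A one-row data.frame: SNP, TOTAL_OR, DIRECT_OR, INDIRECT_OR, PM,
#'   ADJ_Z, ADJ_P, MEDIATED, UNDEFINED_PM; with `per_gene`, an attribute
#'   `per_gene` holding the per-gene records.
#' @export
proportion_mediated <- function(index_record, model_snps, ld, z,
                                per_gene = NULL) {
  if (!length(model_snps)) .stopf("adjusting model-SNP set is empty")
  # the index variant may itself be a model SNP; conditioning on itself is
  # the collinearity path and yields a null direct effect (full mediation)
  one <- function(snps) {
    zi <- stats::setNames(index_record$Z, index_record$SNP)
    adj <- conditional_z(zi, snps, ld, z_index = z)
    total_or <- exp(index_record$BETA)
    direct_beta <- adj$Z_ADJ * index_record$SE
    direct_or <- exp(direct_beta)
    undefined <- abs(total_or - 1) < 1e-6
    indirect_or <- total_or / direct_or
    pm <- if (undefined) NA_real_ else pm_formula(total_or, direct_or)
    adj_p <- .z2p(adj$Z_ADJ)
    data.frame(SNP = index_record$SNP, TOTAL_OR = total_or,
               DIRECT_OR = direct_or, INDIRECT_OR = indirect_or, PM = pm,
               ADJ_Z = adj$Z_ADJ, ADJ_P = adj_p,
               MEDIATED = isTRUE(pm > 0.5 && adj_p > 5e-8),
               UNDEFINED_PM = undefined, stringsAsFactors = FALSE)
  }
  rec <- one(model_snps)
  if (!is.null(per_gene))
    attr(rec, "per_gene") <- do.call(rbind, lapply(per_gene, one))
  rec
}
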