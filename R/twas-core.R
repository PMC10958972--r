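#' Summary-based TWAS z-score for one feature in one tissue
#'
#' Computes the S-PrediXcan-type association z-score of a genetically
#' predicted feature (gene expression or intron excision) with the trait:
#' `z_g = sum_l w_l (sigma_l / sigma_g) z_l` with
#' `sigma_g^2 = w' Gamma w`, where `w` are the model weights, `z_l` the
#' per-SNP GWAS z-scores, and `sigma_l`, `Gamma` the SNP dosage SDs and
#' covariance from the LD reference. Model SNPs without a usable z are
#' dropped and `sigma_g` is recomputed over the SNPs used; coverage is
#' reported so low-coverage results can be filtered.
#'
#' @param model One (feature, tissue) weight data.frame (columns SNP,
#'   weight, plus feature metadata), as stored in a `model_set`.
#' @param z Named vector of (observed or imputed) z-scores.
#' @param ld An `ld_block` covering the model SNPs.
#' @return A one-row data.frame: feature_id, feature_type, gene_id, tissue,
#'   Z, P, NSNP_MODEL, NSNP_USED, SIGMA_G, FLAGS (`ok`, `low_coverage` or
#'   `untestable`).
#' @examples
#' panel <- sim_genotypes(500, ld_spec(1, 2, 0), seed = 1)
#' ld <- build_ld(panel)
#' m <- data.frame(feature_id = "g1", feature_type = "gene", gene_id = "g1",
#'                 tissue = "breast", SNP = panel$map$SNP[1], weight = 1)
#' twas_zscore(m, stats::setNames(2, panel$map$SNP[1]), ld)
#' @export
twas_zscore <- function(model, z, ld) {
  st <- .twas_zscore_fast(model$SNP, model$weight, z, ld)
  data.frame(feature_id = model$feature_id[1],
             feature_type = model$feature_type[1],
             gene_id = model$gene_id[1], tissue = model$tissue[1],
             Z = st$z, P = st$p, NSNP_MODEL = st$n_model,
             NSNP_USED = st$n_used, SIGMA_G = st$sigma_g, FLAGS = st$flag,
             stringsAsFactors = FALSE)
}

# Core arithmetic shared by twas_zscore() and the vectorized per-tissue scan.
.twas_zscore_fast <- function(snps, w, z, ld) {
  n_model <- length(snps)
  zz <- z[match(snps, names(z))]
  use <- is.finite(zz)
  n_used <- sum(use)
  if (n_used == 0)
    return(list(z = NA_real_, p = NA_real_, sigma_g = NA_real_,
                n_model = n_model, n_used = 0L, flag = "untestable"))
  s <- snps[use]; wu <- w[use]; zu <- zz[use]
  idx <- .ld_index(ld, s)
  sig <- ld$sigma[idx]
  var_g <- drop(crossprod(wu, ld$Gamma[idx, idx, drop = FALSE] %*% wu))
  if (!is.finite(var_g) || var_g <= 0)
    return(list(z = NA_real_, p = NA_real_, sigma_g = NA_real_,
                n_model = n_model, n_used = n_used, flag = "untestable"))
  sigma_g <- sqrt(var_g)
  zg <- sum(wu * sig * zu) / sigma_g
  flag <- if (n_used < n_model && n_used / n_model < 0.5) "low_coverage" else "ok"
  list(z = zg, p = .z2p(zg), sigma_g = sigma_g, n_model = n_model,
       n_used = as.integer(n_used), flag = flag)
}

#' Run the TWAS for every feature of one tissue
#'
#' Applies [twas_zscore()] to each (feature, tissue) model of the given
#' tissue, expression and splicing features alike, resolving each feature to
#' its LD region. Features whose region is missing are skipped with a
#' message; ordering is deterministic by feature id.
#'
#' @param model_set A `model_set`.
#' @param z Named z-score vector (observed plus imputed) covering model
#'   SNPs, or a list of such vectors keyed by region id.
#' @param ld_blocks A single `ld_block` or a named list of `ld_block`s keyed
#'   by region id.
#' @param tissue Tissue id to scan.
#' @param region_of Optional named character vector mapping feature_id to
#'   region id; required when `ld_blocks` is a list and features do not all
#'   share one region.
#' @return A data.frame with one row per feature (columns as in
#'   [twas_zscore()]).
#' @export
run_tissue_twas <- function(model_set, z, ld_blocks, tissue, region_of = NULL) {
  keys <- names(model_set$models)
  keys <- keys[endsWith(keys, paste0("|", tissue))]
  keys <- keys[order(sub("\\|.*$", "", keys))]
  single <- inherits(ld_blocks, "ld_block")
  n <- length(keys)
  fid <- character(n); ftype <- character(n); gid <- character(n)
  zg <- numeric(n); pg <- numeric(n); nm <- integer(n); nu <- integer(n)
  sg <- numeric(n); fl <- character(n); keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    d <- model_set$models[[keys[i]]]
    fid[i] <- d$feature_id[1]; ftype[i] <- d$feature_type[1]; gid[i] <- d$gene_id[1]
    if (single) {
      ld <- ld_blocks
      zr <- z
    } else {
      reg <- if (!is.null(region_of)) region_of[[fid[i]]] else names(ld_blocks)[1]
      ld <- ld_blocks[[reg]]
      zr <- if (is.list(z) && !is.null(names(z)) && reg %in% names(z)) z[[reg]] else z
      if (is.null(ld)) { keep[i] <- FALSE; next }
    }
    st <- .twas_zscore_fast(d$SNP, d$weight, zr, ld)
    zg[i] <- st$z; pg[i] <- st$p; nm[i] <- st$n_model; nu[i] <- st$n_used
    sg[i] <- st$sigma_g; fl[i] <- st$flag
  }
  if (any(!keep)) message(sprintf("skipped %d feature(s) without an LD region", sum(!keep)))
  data.frame(feature_id = fid, feature_type = ftype, gene_id = gid,
             tissue = tissue, Z = zg, P = pg, NSNP_MODEL = nm, NSNP_USED = nu,
             SIGMA_G = sg, FLAGS = fl, stringsAsFactors = FALSE)[keep, , drop = FALSE]
}
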