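#' Specify a block-diagonal AR(1) LD structure
#'
#' Describes the linkage-disequilibrium structure used by [sim_genotypes()]:
#' independent blocks of SNPs whose latent (copula) correlation decays as
#' `rho^|i-j|` within a block, with minor-allele frequencies drawn uniformly
#' from `maf_range`.
#'
#' @param n_blocks Number of independent LD blocks.
#' @param block_size Number of SNPs per block.
#' @param rho Within-block AR(1) latent correlation, in `[0, 1)`.
#' @param maf_range Length-2 numeric, minor-allele frequency range in `(0, 0.5]`.
#' @return An object of class `ld_spec`.
#' @examples
#' ld_spec(n_blocks = 2, block_size = 5, rho = 0.7)
#' @export
ld_spec <- function(n_blocks, block_size, rho, maf_range = c(0.05, 0.5)) {
  if (!.is_count(n_blocks) || !.is_count(block_size))
    .stopf("n_blocks and block_size must be positive integers")
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1)
    .stopf("rho must be in [0, 1)")
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    .stopf("maf_range must be an increasing pair within (0, 0.5]")
  structure(
    list(n_blocks = as.integer(n_blocks), block_size = as.integer(block_size),
         rho = rho, maf_range = as.numeric(maf_range)),
    class = "ld_spec"
  )
}

#' @export
print.ld_spec <- function(x, ...) {
  cat(sprintf("LD spec: %d block(s) x %d SNPs, AR(1) rho = %g, MAF in [%g, %g]\n",
              x$n_blocks, x$block_size, x$rho, x$maf_range[1], x$maf_range[2]))
  invisible(x)
}

# Draw one n x m haplotype-pair dosage panel for given per-SNP MAFs, using a
# Gaussian copula with AR(1) latent correlation within each block. Each of the
# two haplotypes is an independent copula draw thresholded at qnorm(maf), so
# dosages are marginally Binomial(2, maf) and LD is shared across haplotypes.
.sim_dosage <- function(n, spec, maf) {
  m <- spec$n_blocks * spec$block_size
  stopifnot(length(maf) == m)
  thr <- stats::qnorm(maf)
  dosage <- matrix(0L, n, m)
  for (hap in 1:2) {
    lat <- matrix(0, n, m)
    for (b in seq_len(spec$n_blocks)) {
      cols <- ((b - 1L) * spec$block_size + 1L):(b * spec$block_size)
      z <- stats::rnorm(n)
      lat[, cols[1]] <- z
      if (spec$block_size > 1L) {
        sc <- sqrt(1 - spec$rho^2)
        for (j in 2:spec$block_size) {
          z <- spec$rho * z + sc * stats::rnorm(n)
          lat[, cols[j]] <- z
        }
      }
    }
    dosage <- dosage + (lat < rep(thr, each = n))
  }
  dosage
}

#' Simulate an LD-structured genotype dosage panel
#'
#' Generates an `n` x `m` dosage matrix (values 0/1/2) by thresholding a
#' Gaussian copula with block-AR(1) correlation into per-haplotype alleles,
#' so each SNP is marginally Binomial(2, MAF) and SNPs within a block are in
#' LD. Blocks are placed 3 Mb apart so a +/- 2 Mb window never spans blocks.
#'
#' @param n Number of individuals (>= 2).
#' @param spec An [ld_spec()] object.
#' @param seed Integer seed; the panel is reproducible given the seed.
#' @return An object of class `geno_panel`: a list with `dosage` (n x m
#'   integer matrix, columns named by SNP id), `map` (data.frame with SNP,
#'   CHR, POS, A1, A2, MAF, BLOCK; A1 is the dosage-counted effect allele),
#'   and the originating `spec`.
#' @examples
#' panel <- sim_genotypes(100, ld_spec(2, 4, 0.5), seed = 1)
#' dim(panel$dosage)
#' @export
sim_genotypes <- function(n, spec, seed) {
  if (!.is_count(n) || n < 2) .stopf("n must be an integer >= 2")
  if (!inherits(spec, "ld_spec")) .stopf("spec must be an ld_spec object")
  set.seed(seed)
  m <- spec$n_blocks * spec$block_size
  maf <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
  # non-palindromic allele pairs only, so harmonization keeps every SNP
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                    "G", "A", "C", "A", "G", "T", "C", "T"),
                  ncol = 2, byrow = TRUE)
  pick <- sample.int(nrow(pairs), m, replace = TRUE)
  block <- rep(seq_len(spec$n_blocks), each = spec$block_size)
  within <- rep(seq_len(spec$block_size), spec$n_blocks)
  map <- data.frame(
    SNP = sprintf("snp_b%04d_%03d", block, within),
    CHR = 1L,
    POS = (block - 1) * 3e6 + within * 1000,
    A1 = pairs[pick, 1], A2 = pairs[pick, 2],
    MAF = maf, BLOCK = block,
    stringsAsFactors = FALSE
  )
  dosage <- .sim_dosage(n, spec, maf)
  colnames(dosage) <- map$SNP
  structure(list(dosage = dosage, map = map, spec = spec, seed = seed),
            class = "geno_panel")
}

#' @export
print.geno_panel <- function(x, ...) {
  cat(sprintf("Genotype panel: %d individuals x %d SNPs (%d block(s) of %d)\n",
              nrow(x$dosage), ncol(x$dosage), x$spec$n_blocks, x$spec$block_size))
  invisible(x)
}

#' Simulate sparse multi-tissue expression and splicing weight models
#'
#' Builds, for each gene, a sparse SNP-weight vector within one LD block,
#' shared across tissues up to tissue-specific Gaussian noise (emulating
#' cross-tissue eQTL effect sharing), plus 1-5 intron-excision features per
#' gene with their own sparse weights in the same block. A subset of genes
#' can be made causal for the trait with log-odds effect `alpha` per SD of
#' the genetic feature score, acting through the expression weights or (for
#' splicing-driven signals) through the first intron's weights.
#'
#' @param panel A `geno_panel` from [sim_genotypes()].
#' @param n_genes Number of genes.
#' @param n_tissues Number of tissues; the roster is `breast` plus
#'   `tissue_02`, ... (11 by default, the size of the breast-cancer-relevant
#'   tissue roster the pipeline mirrors).
#' @param sparsity Causal model SNPs per feature (must not exceed the block
#'   size).
#' @param weight_sd SD of tissue-specific noise added to the shared base
#'   weights (0 gives identical weights in all tissues).
#' @param introns_per_gene Length-2 integer range for the number of intron
#'   features per gene.
#' @param n_causal Number of causal genes (0 for a fully null set).
#' @param alpha Log-odds trait effect per SD of genetic score for causal
#'   genes (recycled).
#' @param causal_channel `"expression"` or `"splicing"`: whether causal
#'   genes act through their expression weights or their first intron's
#'   weights.
#' @param seed Integer seed.
#' @return A list with `weights` (long-format weight table: feature_id,
#'   feature_type, gene_id, tissue, SNP, A1, A2, weight), `intron_map`
#'   (intron_id, gene_id) and `truth` (class `truth_table`: per-gene causal
#'   flags, effects, causal SNP sets and the weight vectors that generate
#'   the phenotype).
#' @export
sim_models <- function(panel, n_genes, n_tissues = 11, sparsity = 2,
                       weight_sd = 0.1, introns_per_gene = c(1L, 3L),
                       n_causal = 0, alpha = 0.05,
                       causal_channel = c("expression", "splicing"),
                       seed = 1) {
  if (!inherits(panel, "geno_panel")) .stopf("panel must be a geno_panel")
  if (!.is_count(n_genes) || !.is_count(n_tissues)) .stopf("n_genes and n_tissues must be positive integers")
  causal_channel <- match.arg(causal_channel)
  bs <- panel$spec$block_size
  if (sparsity < 1) .stopf("sparsity must be >= 1 causal SNP per feature")
  if (sparsity > bs)
    .stopf("requested %d causal SNPs but blocks contain only %d SNPs", sparsity, bs)
  if (n_causal > n_genes) .stopf("n_causal exceeds n_genes")
  set.seed(seed)

  tissues <- c("breast", if (n_tissues > 1) sprintf("tissue_%02d", 2:n_tissues))
  gene_block <- ((seq_len(n_genes) - 1L) %% panel$spec$n_blocks) + 1L
  gene_id <- sprintf("GENE%04d", seq_len(n_genes))
  causal <- rep(FALSE, n_genes)
  if (n_causal > 0) causal[sample.int(n_genes, n_causal)] <- TRUE
  alpha_vec <- ifelse(causal, rep_len(alpha, n_genes), 0)

  n_int <- sample(introns_per_gene[1]:introns_per_gene[2], n_genes, replace = TRUE)

  rows <- vector("list", n_genes)
  causal_weights <- vector("list", n_genes)
  names(causal_weights) <- gene_id
  intron_map <- vector("list", n_genes)

  feature_rows <- function(fid, ftype, gid, snp_idx, base) {
    snps <- panel$map[snp_idx, , drop = FALSE]
    out <- vector("list", length(tissues))
    for (t in seq_along(tissues)) {
      w <- base + stats::rnorm(length(base), 0, weight_sd)
      w[w == 0] <- 1e-6  # keep every weight nonzero
      out[[t]] <- data.frame(
        feature_id = fid, feature_type = ftype, gene_id = gid,
        tissue = tissues[t], SNP = snps$SNP, A1 = snps$A1, A2 = snps$A2,
        weight = w, stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  }

  for (g in seq_len(n_genes)) {
    b <- gene_block[g]
    block_idx <- which(panel$map$BLOCK == b)
    gsnp <- sort(sample(block_idx, sparsity))
    gbase <- stats::rnorm(sparsity, 0, 1)
    gbase[gbase == 0] <- 1e-6
    parts <- list(feature_rows(gene_id[g], "gene", gene_id[g], gsnp, gbase))
    ints <- character(n_int[g])
    ibase1 <- NULL
    for (i in seq_len(n_int[g])) {
      iid <- sprintf("%s_int%02d", gene_id[g], i)
      ints[i] <- iid
      isnp <- sort(sample(block_idx, sparsity))
      ibase <- stats::rnorm(sparsity, 0, 1)
      ibase[ibase == 0] <- 1e-6
      if (i == 1L) ibase1 <- list(snp = isnp, w = ibase)
      parts[[i + 1L]] <- feature_rows(iid, "intron", gene_id[g], isnp, ibase)
    }
    rows[[g]] <- do.call(rbind, parts)
    intron_map[[g]] <- data.frame(intron_id = ints, gene_id = gene_id[g],
                                  stringsAsFactors = FALSE)
    causal_weights[[g]] <-
      if (causal_channel == "expression" || is.null(ibase1))
        data.frame(SNP = panel$map$SNP[gsnp], weight = gbase, stringsAsFactors = FALSE)
      else
        data.frame(SNP = panel$map$SNP[ibase1$snp], weight = ibase1$w, stringsAsFactors = FALSE)
  }

  truth <- structure(
    list(
      genes = data.frame(gene_id = gene_id, block = gene_block, causal = causal,
                         alpha = alpha_vec, channel = causal_channel,
                         stringsAsFactors = FALSE),
      causal_weights = causal_weights,
      tissues = tissues
    ),
    class = "truth_table"
  )
  list(weights = do.call(rbind, rows), intron_map = do.call(rbind, intron_map),
       truth = truth)
}

# Per-SNP joint effect on the log-odds (dosage scale) implied by a truth table.
.joint_dosage_effects <- function(panel, truth) {
  beta <- stats::setNames(numeric(nrow(panel$map)), panel$map$SNP)
  for (g in which(truth$genes$causal)) {
    cw <- truth$causal_weights[[truth$genes$gene_id[g]]]
    if (is.null(cw) || nrow(cw) == 0)
      .stopf("gene %s has nonzero effect but no weights", truth$genes$gene_id[g])
    X <- panel$dosage[, cw$SNP, drop = FALSE]
    sigma_g <- sqrt(drop(crossprod(cw$weight, stats::cov(X) %*% cw$weight)))
    beta[cw$SNP] <- beta[cw$SNP] + truth$genes$alpha[g] * cw$weight / sigma_g
  }
  beta
}

#' Simulate case-control GWAS summary statistics
#'
#' Produces one marginal-association record per panel SNP, either by drawing
#' the z-score vector directly from its asymptotic distribution
#' `z ~ N(sqrt(Neff)/2 * R lambda, R)` per LD block (`mode = "direct"`, with
#' `lambda` the joint standardized log-odds effects and
#' `Neff = 4 / (1/n_cases + 1/n_controls)`), or by simulating individual
#' genotypes and a logistic disease phenotype and computing the per-SNP
#' logistic score-test z (`mode = "individual"`). The two samplers agree in
#' expectation; the individual-level route serves as the calibration oracle
#' for the fast direct route.
#'
#' @param panel A `geno_panel`.
#' @param truth A `truth_table` from [sim_models()].
#' @param n_cases,n_controls Case and control counts.
#' @param mode `"direct"` or `"individual"`.
#' @param seed Integer seed.
#' @return A data.frame of summary statistics (SNP, CHR, POS, A1, A2, BETA,
#'   SE, Z, P, N) that passes [validate_sumstats()]. BETA is the log
#'   odds-ratio for allele A1.
#' @export
sim_gwas <- function(panel, truth, n_cases, n_controls,
                     mode = c("direct", "individual"), seed = 1) {
  mode <- match.arg(mode)
  if (!inherits(panel, "geno_panel")) .stopf("panel must be a geno_panel")
  if (!.is_count(n_cases) || !.is_count(n_controls))
    .stopf("n_cases and n_controls must be positive integers")
  set.seed(seed)
  beta_dos <- .joint_dosage_effects(panel, truth)
  map <- panel$map
  n_total <- n_cases + n_controls
  neff <- 4 / (1 / n_cases + 1 / n_controls)
  sd_l <- apply(panel$dosage, 2, stats::sd)
  if (any(sd_l == 0)) .stopf("panel contains monomorphic SNPs; increase n or MAF")

  if (mode == "direct") {
    z <- numeric(nrow(map))
    for (b in unique(map$BLOCK)) {
      idx <- which(map$BLOCK == b)
      R <- stats::cor(panel$dosage[, idx, drop = FALSE])
      mu <- sqrt(neff) / 2 * drop(R %*% (beta_dos[idx] * sd_l[idx]))
      ch <- chol(R + diag(1e-8, length(idx)))
      z[idx] <- mu + drop(crossprod(ch, stats::rnorm(length(idx))))
    }
  } else {
    phi <- n_cases / n_total
    X <- .sim_dosage(n_total, panel$spec, map$MAF)
    eta <- stats::qlogis(phi) + drop(sweep(X, 2, 2 * map$MAF) %*% beta_dos)
    y <- stats::rbinom(n_total, 1, stats::plogis(eta))
    sx <- apply(X, 2, stats::sd)
    if (any(sx == 0)) .stopf("simulated cohort contains monomorphic SNPs")
    z <- drop(stats::cor(X, y)) * sqrt(n_total)
  }

  se <- 2 / (sqrt(neff) * sd_l)
  data.frame(
    SNP = map$SNP, CHR = map$CHR, POS = map$POS, A1 = map$A1, A2 = map$A2,
    BETA = unname(z * se), SE = unname(se), Z = unname(z), P = unname(.z2p(z)),
    N = n_total, row.names = NULL, stringsAsFactors = FALSE
  )
}

.fixture_scenarios <- c("null", "single_gene", "multi_tissue", "splicing_only",
                        "mediation", "finemap_pair", "masked_snps")

#' Write a named synthetic scenario to disk
#'
#' Generates a complete input bundle for the pipeline - summary statistics,
#' weight table, intron map, per-block LD matrices with variant sidecars, an
#' index-SNP list and a ground-truth JSON - for one of the named scenarios.
#' Scenario defaults (sample sizes 30,882 cases / 115,468 controls, tissue
#' roster, effect sizes) are fixed study conditions; see the package
#' vignette for their rationale.
#'
#' @param outdir Output directory (created if needed).
#' @param scenario One of `"null"`, `"single_gene"`, `"multi_tissue"`,
#'   `"splicing_only"`, `"mediation"`, `"finemap_pair"`, `"masked_snps"`.
#' @param seed Integer seed.
#' @param n_genes,n_tissues Optional overrides of the scenario defaults.
#' @return (Invisibly) a list with the written `paths` and the in-memory
#'   `truth`, `panel` and `weights`.
#' @export
make_fixtures <- function(outdir, scenario, seed = 1, n_genes = NULL,
                          n_tissues = NULL) {
  if (!scenario %in% .fixture_scenarios)
    .stopf("unknown scenario '%s'; valid: %s", scenario,
           paste(.fixture_scenarios, collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "ld"), recursive = TRUE, showWarnings = FALSE)

  n_cases <- 30882L
  n_controls <- 115468L
  def <- switch(scenario,
    null          = list(genes = 2000L, tissues = 3L,  blocks = NULL, bs = 4L,
                         rho = 0.7, ncausal = 0L, alpha = 0,    sparsity = 2L,
                         introns = c(1L, 2L), channel = "expression"),
    single_gene   = list(genes = 20L,   tissues = 11L, blocks = NULL, bs = 6L,
                         rho = 0.7, ncausal = 1L, alpha = 0.05, sparsity = 2L,
                         introns = c(1L, 3L), channel = "expression"),
    multi_tissue  = list(genes = 20L,   tissues = 11L, blocks = NULL, bs = 6L,
                         rho = 0.7, ncausal = 3L, alpha = 0.05, sparsity = 2L,
                         introns = c(1L, 3L), channel = "expression"),
    splicing_only = list(genes = 20L,   tissues = 11L, blocks = NULL, bs = 6L,
                         rho = 0.7, ncausal = 1L, alpha = 0.05, sparsity = 2L,
                         introns = c(1L, 3L), channel = "splicing"),
    mediation     = list(genes = 10L,   tissues = 11L, blocks = NULL, bs = 6L,
                         rho = 0.7, ncausal = 1L, alpha = 0.05, sparsity = 1L,
                         introns = c(1L, 2L), channel = "expression"),
    finemap_pair  = list(genes = 2L,    tissues = 11L, blocks = 1L,   bs = 6L,
                         rho = 0.8, ncausal = 1L, alpha = 0.05, sparsity = 3L,
                         introns = c(1L, 1L), channel = "expression"),
    masked_snps   = list(genes = 20L,   tissues = 11L, blocks = NULL, bs = 6L,
                         rho = 0.7, ncausal = 1L, alpha = 0.05, sparsity = 2L,
                         introns = c(1L, 2L), channel = "expression")
  )
  if (!is.null(n_genes)) def$genes <- as.integer(n_genes)
  if (!is.null(n_tissues)) def$tissues <- as.integer(n_tissues)
  if (is.null(def$blocks)) def$blocks <- def$genes

  spec <- ld_spec(def$blocks, def$bs, def$rho)
  panel <- sim_genotypes(500, spec, seed = seed)

  mod <- sim_models(panel, n_genes = def$genes, n_tissues = def$tissues,
                    sparsity = def$sparsity, weight_sd = 0.1,
                    introns_per_gene = def$introns, n_causal = def$ncausal,
                    alpha = def$alpha, causal_channel = def$channel,
                    seed = seed + 1L)

  if (scenario == "finemap_pair") {
    # second gene's expression weights track the first gene's so the two
    # predicted expressions are strongly correlated within the block
    w <- mod$weights
    g1 <- w[w$feature_id == "GENE0001" & w$feature_type == "gene", ]
    g2rows <- w$feature_id == "GENE0002" & w$feature_type == "gene"
    set.seed(seed + 2L)
    for (t in unique(w$tissue)) {
      src <- g1[g1$tissue == t, ]
      sel <- which(g2rows & w$tissue == t)
      w$SNP[sel] <- src$SNP
      w$A1[sel] <- src$A1
      w$A2[sel] <- src$A2
      w$weight[sel] <- src$weight + stats::rnorm(nrow(src), 0, 0.25)
    }
    mod$weights <- w
    # keep the generative truth aligned with the rewritten model
    g2b <- w[w$feature_id == "GENE0002" & w$feature_type == "gene" &
               w$tissue == "breast", ]
    mod$truth$causal_weights[["GENE0002"]] <-
      data.frame(SNP = g2b$SNP, weight = g2b$weight, stringsAsFactors = FALSE)
  }

  if (scenario == "mediation") {
    # the causal gene's single eQTL is also the GWAS index SNP
    gcausal <- mod$truth$genes$gene_id[mod$truth$genes$causal][1]
    index_snp <- mod$truth$causal_weights[[gcausal]]$SNP[1]
  } else index_snp <- character(0)

  sums <- sim_gwas(panel, mod$truth, n_cases, n_controls, mode = "direct",
                   seed = seed + 3L)

  masked <- character(0)
  if (scenario == "masked_snps") {
    model_snps <- unique(mod$weights$SNP)
    set.seed(seed + 4L)
    masked <- sample(model_snps, ceiling(0.25 * length(model_snps)))
    sums <- sums[!sums$SNP %in% masked, , drop = FALSE]
  }

  paths <- list(
    sumstats = file.path(outdir, "sumstats.tsv"),
    weights = file.path(outdir, "weights.tsv"),
    intron_map = file.path(outdir, "intron_map.tsv"),
    index_snps = file.path(outdir, "index_snps.tsv"),
    truth = file.path(outdir, "truth.json"),
    ld_dir = file.path(outdir, "ld")
  )
  write_sumstats(sums, paths$sumstats)
  utils::write.table(mod$weights, paths$weights, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(mod$intron_map, paths$intron_map, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  idx_df <- if (length(index_snp)) {
    mi <- match(index_snp, panel$map$SNP)
    data.frame(SNP = index_snp, CHR = panel$map$CHR[mi], POS = panel$map$POS[mi],
               LOCUS = sprintf("locus_%02d", seq_along(index_snp)),
               SUBTYPE = "ERPOS", stringsAsFactors = FALSE)
  } else {
    data.frame(SNP = character(0), CHR = integer(0), POS = integer(0),
               LOCUS = character(0), SUBTYPE = character(0))
  }
  utils::write.table(idx_df, paths$index_snps, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (b in unique(panel$map$BLOCK)) {
    ld <- build_ld(panel, panel$map$SNP[panel$map$BLOCK == b])
    write_ld(ld, file.path(outdir, "ld", sprintf("block_%04d", b)))
  }
  truth_json <- list(
    scenario = scenario, seed = seed,
    n_cases = n_cases, n_controls = n_controls,
    genes = mod$truth$genes,
    causal_genes = mod$truth$genes$gene_id[mod$truth$genes$causal],
    masked_snps = masked,
    index_snps = index_snp
  )
  jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, truth = mod$truth, panel = panel,
                 weights = mod$weights, intron_map = mod$intron_map,
                 sumstats = sums, masked = masked))
}
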