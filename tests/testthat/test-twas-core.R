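test_that("single-SNP TWAS reduces to the SNP z-score", {
  ld <- exact_ld(diag(1), sigma = 1.3)
  m <- weight_model("g1", "s1", 1)
  res <- twas_zscore(m, c(s1 = 2.2), ld)
  expect_equal(res$Z, 2.2, tolerance = 1e-12)
  expect_identical(res$FLAGS, "ok")
  expect_equal(res$P, 2 * pnorm(-2.2))
})

test_that("two independent standardized SNPs combine as z / sqrt(2)", {
  ld <- exact_ld(diag(2))
  m <- weight_model("g1", c("s1", "s2"), c(1, 1))
  res <- twas_zscore(m, c(s1 = 2, s2 = 0), ld)
  expect_equal(res$Z, 2 / sqrt(2), tolerance = 1e-12)
  expect_equal(res$Z, 1.41421, tolerance = 1e-5)
  expect_equal(res$SIGMA_G, sqrt(2))
})

test_that("the statistic is scale-invariant and sign-equivariant in the weights", {
  panel <- sim_genotypes(300, ld_spec(1, 5, 0.6), seed = 41)
  ld <- build_ld(panel)
  set.seed(42)
  w <- rnorm(5)
  z <- stats::setNames(rnorm(5), ld$snps$SNP)
  m <- weight_model("g1", ld$snps$SNP, w)
  base <- twas_zscore(m, z, ld)$Z
  m_scaled <- m; m_scaled$weight <- 7.3 * w
  expect_equal(twas_zscore(m_scaled, z, ld)$Z, base, tolerance = 1e-10)
  m_neg <- m; m_neg$weight <- -w
  expect_equal(twas_zscore(m_neg, z, ld)$Z, -base, tolerance = 1e-10)
})

test_that("missing-SNP policy drops, renormalizes and flags coverage", {
  ld <- exact_ld(diag(3))
  m <- weight_model("g1", c("s1", "s2", "s3"), c(1, 1, 1))
  res <- twas_zscore(m, c(s1 = 3), ld)   # 1/3 coverage
  expect_equal(res$Z, 3, tolerance = 1e-12)  # sigma_g recomputed over s1 only
  expect_identical(res$NSNP_USED, 1L)
  expect_identical(res$FLAGS, "low_coverage")
  res_none <- twas_zscore(m, c(other = 1), ld)
  expect_identical(res_none$FLAGS, "untestable")
  expect_true(is.na(res_none$Z))
})

test_that("summary-based z matches the null distribution", {
  # z_g over >= 5000 simulated null features is N(0,1)
  set.seed(43)
  n_blocks <- 1000
  spec <- ld_spec(n_blocks, 5, 0.7)
  panel <- sim_genotypes(500, spec, seed = 43)
  mod <- sim_models(panel, n_genes = n_blocks, n_tissues = 1, sparsity = 3,
                    introns_per_gene = c(1, 1), seed = 44)
  ms <- load_models(mod$weights, mod$intron_map)
  lds <- lapply(split(panel$map$SNP, panel$map$BLOCK),
                function(s) build_ld(panel, s))
  names(lds) <- paste0("b", seq_along(lds))
  zg <- numeric(0)
  for (rep_i in 1:3) {
    sums <- sim_gwas(panel, mod$truth, 20000, 20000, "direct", seed = 50 + rep_i)
    z <- stats::setNames(sums$Z, sums$SNP)
    for (b in seq_len(n_blocks)) {
      key <- paste0(mod$truth$genes$gene_id[b], "|breast")
      st <- twas_zscore(ms$models[[key]], z, lds[[b]])
      zg <- c(zg, st$Z)
    }
  }
  expect_gte(length(zg), 3000)
  expect_lt(abs(mean(zg)), 4 / sqrt(length(zg)))
  expect_equal(sd(zg), 1, tolerance = 0.05)
})

test_that("the causal gene attains the minimum p-value in its tissue", {
  spec <- ld_spec(20, 6, 0.7)
  panel <- sim_genotypes(500, spec, seed = 45)
  mod <- sim_models(panel, 20, n_tissues = 1, sparsity = 2, n_causal = 1,
                    alpha = 0.05, seed = 46)
  ms <- load_models(mod$weights, mod$intron_map)
  lds <- lapply(split(panel$map$SNP, panel$map$BLOCK),
                function(s) build_ld(panel, s))
  names(lds) <- paste0("b", seq_along(lds))
  region_of <- stats::setNames(paste0("b", mod$truth$genes$block),
                               mod$truth$genes$gene_id)
  for (f in ms$features$feature_id)
    region_of[f] <- region_of[ms$features$gene_id[ms$features$feature_id == f]]
  causal <- mod$truth$genes$gene_id[mod$truth$genes$causal]
  hits <- 0
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    sums <- sim_gwas(panel, mod$truth, 30882, 115468, "direct", seed = 500 + s)
    z <- stats::setNames(sums$Z, sums$SNP)
    res <- run_tissue_twas(ms, z, lds, "breast", region_of = region_of)
    expr <- res[res$feature_type == "gene", ]
    if (expr$gene_id[which.min(expr$P)] == causal) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("per-tissue scans are deterministic and ordered", {
  panel <- sim_genotypes(300, ld_spec(3, 4, 0.5), seed = 47)
  mod <- sim_models(panel, 3, n_tissues = 2, seed = 48)
  ms <- load_models(mod$weights, mod$intron_map)
  ld <- build_ld(panel)
  sums <- sim_gwas(panel, mod$truth, 5000, 5000, "direct", seed = 49)
  z <- stats::setNames(sums$Z, sums$SNP)
  r1 <- run_tissue_twas(ms, z, ld, "breast")
  r2 <- run_tissue_twas(ms, z, ld, "breast")
  expect_identical(r1, r2)
  expect_identical(r1$feature_id, sort(r1$feature_id))
})
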