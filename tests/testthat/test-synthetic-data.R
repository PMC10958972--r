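test_that("ld_spec rejects invalid structures", {
  expect_error(ld_spec(0, 5, 0.5), "positive integers")
  expect_error(ld_spec(2, 5, 1), "rho")
  expect_error(ld_spec(2, 5, 0.5, maf_range = c(0, 0.5)), "maf_range")
  expect_error(ld_spec(2, 5, 0.5, maf_range = c(0.1, 0.6)), "maf_range")
})

test_that("simulated dosages are valid, reproducible and independent at rho = 0", {
  spec <- ld_spec(4, 5, 0)
  p1 <- sim_genotypes(2000, spec, seed = 7)
  p2 <- sim_genotypes(2000, spec, seed = 7)
  expect_identical(p1$dosage, p2$dosage)
  expect_true(all(p1$dosage %in% 0:2))
  expect_identical(colnames(p1$dosage), p1$map$SNP)
  r <- cor(p1$dosage)
  off <- abs(r[upper.tri(r)])
  expect_lt(mean(off), 3 / sqrt(2000))
  expect_error(sim_genotypes(1, spec, seed = 1), ">= 2")
})

test_that("within-block dosage correlation matches the copula integration oracle", {
  spec <- ld_spec(1, 2, 0.9, maf_range = c(0.3, 0.3))
  panel <- sim_genotypes(5000, spec, seed = 11)
  emp <- cor(panel$dosage)[1, 2]
  expect_lt(abs(emp - dosage_cor_oracle(0.9, 0.3, 0.3)), 0.05)
  # and at a lower rho with asymmetric MAFs drawn by the generator
  spec2 <- ld_spec(1, 2, 0.6, maf_range = c(0.1, 0.4))
  panel2 <- sim_genotypes(5000, spec2, seed = 12)
  th <- dosage_cor_oracle(0.6, panel2$map$MAF[1], panel2$map$MAF[2])
  expect_lt(abs(cor(panel2$dosage)[1, 2] - th), 0.05)
})

test_that("weight models share support across tissues and respect preconditions", {
  panel <- sim_genotypes(200, ld_spec(3, 5, 0.5), seed = 1)
  mod <- sim_models(panel, n_genes = 3, n_tissues = 4, sparsity = 2,
                    weight_sd = 0, seed = 2)
  w <- mod$weights
  # zero tissue noise: identical weights in all tissues
  for (f in unique(w$feature_id)) {
    sub <- split(w$weight[w$feature_id == f], w$tissue[w$feature_id == f])
    for (t in sub[-1]) expect_equal(t, sub[[1]])
  }
  # every (feature, tissue) model nonempty with known variant ids
  expect_true(all(w$weight != 0))
  expect_true(all(w$SNP %in% panel$map$SNP))
  key <- paste(w$feature_id, w$tissue)
  expect_true(all(table(key) >= 1))
  expect_error(sim_models(panel, 2, sparsity = 10, seed = 1), "5 SNPs")
})

test_that("direct-mode GWAS z-scores are null-calibrated and deterministic", {
  spec <- ld_spec(500, 2, 0.5)
  panel <- sim_genotypes(800, spec, seed = 3)
  mod <- sim_models(panel, n_genes = 10, n_tissues = 2, seed = 4)
  s1 <- sim_gwas(panel, mod$truth, 5000, 5000, "direct", seed = 5)
  s2 <- sim_gwas(panel, mod$truth, 5000, 5000, "direct", seed = 5)
  expect_identical(s1, s2)
  # 1000 SNPs, all null: per-SNP z pooled should be ~N(0,1)
  expect_lt(abs(mean(s1$Z)), 3 / sqrt(nrow(s1)) * 1.5)  # LD inflates slightly
  expect_equal(sd(s1$Z), 1, tolerance = 0.08)
  expect_equal(validate_sumstats(s1), s1)
})

test_that("individual-level and direct samplers agree at the causal SNP", {
  spec <- ld_spec(1, 4, 0.6)
  panel <- sim_genotypes(600, spec, seed = 6)
  mod <- sim_models(panel, n_genes = 1, n_tissues = 1, sparsity = 1,
                    n_causal = 1, alpha = 0.15, seed = 7)
  causal_snp <- mod$truth$causal_weights[[1]]$SNP[1]
  zd <- zi <- numeric(200)
  for (r in 1:200) {
    sd_ <- sim_gwas(panel, mod$truth, 1500, 1500, "direct", seed = 100 + r)
    si <- sim_gwas(panel, mod$truth, 1500, 1500, "individual", seed = 300 + r)
    zd[r] <- sd_$Z[sd_$SNP == causal_snp]
    zi[r] <- si$Z[si$SNP == causal_snp]
  }
  # means agree within Monte-Carlo error (SE ~ 1/sqrt(200) each)
  expect_gt(abs(mean(zd)), 2)  # the signal is really there (sign follows the weight)
  expect_lt(abs(mean(zd) - mean(zi)), 4 / sqrt(200))
})

test_that("alpha without weights is an inconsistency error", {
  panel <- sim_genotypes(100, ld_spec(1, 3, 0.5), seed = 1)
  mod <- sim_models(panel, 1, n_tissues = 1, n_causal = 1, alpha = 0.1, seed = 1)
  mod$truth$causal_weights[[1]] <- mod$truth$causal_weights[[1]][0, ]
  expect_error(sim_gwas(panel, mod$truth, 100, 100, "direct", seed = 1),
               "no weights")
})

test_that("fixture scenarios encode their stated constructions", {
  expect_error(make_fixtures(tempfile(), "no_such_scenario"), "unknown scenario")

  d <- tempfile("fxnull")
  fx <- make_fixtures(d, "null", seed = 1, n_genes = 8)
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_length(truth$causal_genes, 0)
  expect_true(file.exists(fx$paths$sumstats))
  expect_true(file.exists(file.path(d, "ld", "block_0001.ld.tsv")))

  d2 <- tempfile("fxmask")
  fx2 <- make_fixtures(d2, "masked_snps", seed = 2)
  sums <- read_sumstats(fx2$paths$sumstats)
  model_snps <- unique(fx2$weights$SNP)
  frac_masked <- mean(!model_snps %in% sums$SNP)
  expect_gte(frac_masked, 0.20)

  d3 <- tempfile("fxpair")
  fx3 <- make_fixtures(d3, "finemap_pair", seed = 3)
  # predicted-expression correlation > 0.5 by exact w' Gamma w arithmetic
  ld <- read_ld(file.path(d3, "ld", "block_0001"))
  w <- fx3$weights
  for (tis in c("breast")) {
    g1 <- w[w$feature_id == "GENE0001" & w$feature_type == "gene" & w$tissue == tis, ]
    g2 <- w[w$feature_id == "GENE0002" & w$feature_type == "gene" & w$tissue == tis, ]
    w1 <- stats::setNames(rep(0, nrow(ld$snps)), ld$snps$SNP)
    w2 <- w1
    w1[g1$SNP] <- g1$weight; w2[g2$SNP] <- g2$weight
    omega12 <- drop(t(w1) %*% ld$Gamma %*% w2) /
      sqrt(drop(t(w1) %*% ld$Gamma %*% w1) * drop(t(w2) %*% ld$Gamma %*% w2))
    expect_gt(omega12, 0.5)
  }
})
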