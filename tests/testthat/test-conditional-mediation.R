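test_that("conditioning matches two-SNP closed forms", {
  ld <- exact_ld(matrix(c(1, 0.8, 0.8, 1), 2))
  adj <- conditional_z(c(s1 = 4.0), "s2", ld, z_index = c(s2 = 5.0), ridge = 0)
  expect_equal(adj$Z_ADJ, 0, tolerance = 1e-9)  # (4 - 0.8*5)/0.6
  adj2 <- conditional_z(c(s1 = 4.0), "s2", ld, z_index = c(s2 = 2.0), ridge = 0)
  expect_equal(adj2$Z_ADJ, (4 - 0.8 * 2) / sqrt(1 - 0.64), tolerance = 1e-9)
})

test_that("independent indices leave targets unchanged; empty set is identity", {
  ld <- exact_ld(diag(3))
  z <- c(s1 = 2.5, s2 = -1.0)
  adj <- conditional_z(z, "s3", ld, z_index = c(s3 = 4))
  expect_equal(adj$Z_ADJ, unname(z), tolerance = 1e-6)
  adj0 <- conditional_z(z, character(0), ld)
  expect_equal(adj0$Z_ADJ, unname(z))
  expect_false(any(adj0$COLLINEAR))
})

test_that("self-conditioning takes the collinearity path", {
  ld <- exact_ld(matrix(c(1, 0.5, 0.5, 1), 2))
  adj <- conditional_z(c(s1 = 3.0), "s1", ld, z_index = c(s1 = 3.0))
  expect_equal(adj$Z_ADJ, 0)
  expect_true(adj$COLLINEAR)
})

test_that("residualization on fixed indices is a projection", {
  set.seed(61)
  R <- 0.7^abs(outer(1:5, 1:5, "-"))
  ld <- exact_ld(R)
  z <- stats::setNames(rnorm(5, sd = 2), ld$snps$SNP)
  idx <- c("s4", "s5")
  a1 <- conditional_z(z[1:3], idx, ld, z_index = z[4:5], ridge = 0)
  # after conditioning, the indices themselves are fully explained (z = 0);
  # re-applying the residualization leaves the residual component unchanged
  cvar <- 1 - rowSums((ld$R[1:3, 4:5] %*% solve(ld$R[4:5, 4:5])) * ld$R[1:3, 4:5])
  num1 <- a1$Z_ADJ * sqrt(cvar)
  a2 <- conditional_z(stats::setNames(num1, a1$SNP), idx, ld,
                      z_index = stats::setNames(c(0, 0), idx), ridge = 0)
  num2 <- a2$Z_ADJ * sqrt(cvar)
  expect_equal(num2, num1, tolerance = 1e-10)
})

test_that("near-duplicate index variants are pruned before inversion", {
  R <- matrix(c(1, 0.99, 0.3,
                0.99, 1, 0.3,
                0.3, 0.3, 1), 3, byrow = TRUE)
  ld <- exact_ld(R)
  adj <- conditional_z(c(s3 = 2.0), c("s1", "s2"), ld,
                       z_index = c(s1 = 5, s2 = 5))
  expect_true(is.finite(adj$Z_ADJ))
  # equals conditioning on s1 alone
  single <- conditional_z(c(s3 = 2.0), "s1", ld, z_index = c(s1 = 5))
  expect_equal(adj$Z_ADJ, single$Z_ADJ, tolerance = 1e-6)
})

test_that("proportion-mediated arithmetic hits its limits and midpoint", {
  expect_equal(pm_formula(1.3, 1.0), 1.0, tolerance = 1e-12)   # full mediation
  expect_equal(pm_formula(1.2, 1.2), 0.0, tolerance = 1e-12)   # no mediation
  expect_equal(pm_formula(1.2, 1.1), 0.5, tolerance = 1e-12)
  expect_error(pm_formula(1.0, 1.0), "undefined")
  # limits are stable under case/control label swap (OR -> 1/OR)
  expect_equal(pm_formula(1 / 1.3, 1.0), 1.0, tolerance = 1e-12)
  expect_equal(pm_formula(1 / 1.2, 1 / 1.2), 0.0, tolerance = 1e-12)
})

test_that("mediation records classify by the PM and significance rule", {
  ld <- exact_ld(matrix(c(1, 0.9, 0.9, 1), 2))
  idx <- data.frame(SNP = "s1", BETA = log(1.3), SE = 0.02,
                    Z = log(1.3) / 0.02, stringsAsFactors = FALSE)
  # conditioning on itself: direct OR 1, PM 1, adjusted p 1 -> mediated
  rec <- proportion_mediated(idx, c("s1", "s2"), ld,
                             z = c(s1 = idx$Z, s2 = 10))
  expect_equal(rec$DIRECT_OR, 1.0)
  expect_equal(rec$PM, 1.0)
  expect_true(rec$MEDIATED)
  expect_error(proportion_mediated(idx, character(0), ld, z = c(s2 = 1)),
               "empty")
  # null total effect: PM undefined
  idx0 <- data.frame(SNP = "s1", BETA = 0, SE = 0.02, Z = 0)
  rec0 <- proportion_mediated(idx0, "s2", ld, z = c(s2 = 1))
  expect_true(rec0$UNDEFINED_PM)
  expect_true(is.na(rec0$PM))
})

test_that("conditional TWAS nulls a gene whose only eQTL is the index SNP", {
  fx <- make_fixtures(tempfile("medfix"), "mediation", seed = 62)
  cfg <- pipeline_config(fx$paths$sumstats, fx$paths$weights,
                         fx$paths$intron_map, fx$paths$ld_dir,
                         fx$paths$index_snps, run_finemap = FALSE)
  suppressWarnings(rep <- run_pipeline(cfg))
  causal <- fx$truth$genes$gene_id[fx$truth$genes$causal]
  cond_p <- rep$conditioned$genes$JOINT_P[
    rep$conditioned$genes$GENE == causal &
      rep$conditioned$genes$APPROACH == "expression"]
  expect_gt(cond_p, 0.9)
  # and the unconditioned signal was genuinely strong
  raw_p <- rep$gene_results$JOINT_P[rep$gene_results$GENE == causal &
                                      rep$gene_results$APPROACH == "expression"]
  expect_lt(raw_p, 1e-6)
})

test_that("indices uncorrelated with model SNPs leave the TWAS unchanged", {
  # exact block-diagonal LD: model SNPs s1-s2, index SNP s4 with r = 0
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.7
  ld <- exact_ld(R)
  w <- rbind(weight_model("g1", c("s1", "s2"), c(1, -0.5), tissue = "breast"),
             weight_model("g1", c("s1", "s2"), c(0.9, -0.4), tissue = "liver"))
  ms <- load_models(w)
  z <- c(s1 = 2.1, s2 = -0.4, s3 = 0.3, s4 = 6.0)
  idx <- data.frame(SNP = "s4", CHR = 1L, POS = ld$snps$POS[4])
  cond <- conditional_twas(ms, z, idx, ld, window = 1e7)
  plain <- rbind(run_tissue_twas(ms, z, ld, "breast"),
                 run_tissue_twas(ms, z, ld, "liver"))
  expect_true(all(cond$results$CONDITIONED))
  for (i in seq_len(nrow(plain))) {
    z_cond <- cond$results$Z[cond$results$feature_id == plain$feature_id[i] &
                               cond$results$tissue == plain$tissue[i]]
    expect_lt(abs(z_cond - plain$Z[i]), 1e-6)  # ridge 1e-6 on R_II
  }
  # conditioned joint p equals unconditioned within tight tolerance
  agg <- aggregate_gene_pvalues(plain, ms)
  expect_equal(cond$genes$JOINT_P, agg$JOINT_P, tolerance = 1e-6)
})
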