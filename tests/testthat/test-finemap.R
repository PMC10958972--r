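test_that("predicted-expression correlation obeys its exact arithmetic", {
  ld <- exact_ld(0.6^abs(outer(1:4, 1:4, "-")), sigma = c(1, 1.2, 0.8, 1))
  m1 <- weight_model("g1", c("s1", "s2"), c(1, 0.5))
  m2 <- weight_model("g2", c("s3", "s4"), c(-0.4, 1))
  ec <- expr_correlation(list(m1, m2), ld, ridge = 0)
  expect_equal(diag(ec$Omega), c(g1 = 1, g2 = 1))
  expect_equal(ec$Omega[1, 2], ec$Omega[2, 1])
  # exact w' Gamma w arithmetic
  w1 <- c(1, 0.5, 0, 0); w2 <- c(0, 0, -0.4, 1)
  expected <- drop(t(w1) %*% ld$Gamma %*% w2) /
    sqrt(drop(t(w1) %*% ld$Gamma %*% w1) * drop(t(w2) %*% ld$Gamma %*% w2))
  expect_equal(unname(ec$Omega[1, 2]), expected, tolerance = 1e-12)
})

test_that("disjoint SNPs in uncorrelated sub-blocks give zero correlation", {
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.5
  R[3, 4] <- R[4, 3] <- 0.5
  ld <- exact_ld(R)
  m1 <- weight_model("g1", c("s1", "s2"), c(1, 1))
  m2 <- weight_model("g2", c("s3", "s4"), c(1, 1))
  ec <- expr_correlation(list(m1, m2), ld, ridge = 0)
  expect_equal(unname(ec$Omega[1, 2]), 0, tolerance = 1e-12)
})

test_that("enumeration PIPs equal the brute-force posterior over all configurations", {
  set.seed(71)
  for (m in 2:4) {
    R <- 0.5^abs(outer(1:m, 1:m, "-"))
    ld <- exact_ld(R)
    mods <- lapply(seq_len(m), function(j)
      weight_model(sprintf("g%d", j), sprintf("s%d", j), 1))
    ec <- expr_correlation(mods, ld, ridge = 0)
    z <- stats::setNames(rnorm(m, sd = 3), ec$features)
    fm <- marginal_pips(z, ec, pi0 = 1e-3, v = 30, k = m)
    bf <- finemap_bruteforce(unname(z), ec$Omega, pi0 = 1e-3, v = 30)
    expect_equal(fm$PIP, bf$pip, tolerance = 1e-10)
    expect_equal(attr(fm, "null_posterior"), bf$null, tolerance = 1e-10)
  }
})

test_that("single-feature regions behave at the null and strong-signal limits", {
  ld <- exact_ld(diag(1))
  ec <- expr_correlation(list(weight_model("g1", "s1", 1)), ld, ridge = 0)
  fm0 <- marginal_pips(c(g1 = 0), ec, pi0 = 1e-3, v = 30)
  expect_lt(fm0$PIP, 1e-3 * 10)  # null dominates
  fm10 <- marginal_pips(c(g1 = 10), ec, pi0 = 1e-3, v = 30)
  expect_gt(fm10$PIP, 0.99)
  expect_true(fm10$CANDIDATE_CAUSAL)
})

test_that("uncorrelated features separate cleanly", {
  ld <- exact_ld(diag(2))
  mods <- list(weight_model("g1", "s1", 1), weight_model("g2", "s2", 1))
  ec <- expr_correlation(mods, ld, ridge = 0)
  fm <- marginal_pips(c(g1 = 10, g2 = 0), ec, pi0 = 1e-3, v = 30, k = 2)
  expect_gt(fm$PIP[fm$FEATURE == "g1"], 0.99)
  expect_lt(fm$PIP[fm$FEATURE == "g2"], 0.01)
})

test_that("credible sets absorb mass correctly at both extremes", {
  ld <- exact_ld(diag(1))
  ec <- expr_correlation(list(weight_model("g1", "s1", 1)), ld, ridge = 0)
  strong <- credible_set(marginal_pips(c(g1 = 10), ec))
  expect_true(strong$IN_CREDIBLE_SET)
  null_fm <- credible_set(marginal_pips(c(g1 = 0.1), ec))
  expect_false(null_fm$IN_CREDIBLE_SET)  # null model absorbs the mass
})

test_that("permuting feature order permutes fine-mapping output consistently", {
  set.seed(72)
  R <- 0.4^abs(outer(1:3, 1:3, "-"))
  ld <- exact_ld(R)
  mods <- list(weight_model("gA", "s1", 1), weight_model("gB", "s2", 1),
               weight_model("gC", "s3", 1))
  z <- c(gA = 5, gB = 1, gC = -2)
  ec1 <- expr_correlation(mods, ld, ridge = 0)
  fm1 <- marginal_pips(z, ec1, k = 3)
  ec2 <- expr_correlation(mods[c(3, 1, 2)], ld, ridge = 0)
  fm2 <- marginal_pips(z, ec2, k = 3)
  expect_equal(fm1$PIP[match(fm2$FEATURE, fm1$FEATURE)], fm2$PIP,
               tolerance = 1e-10)
})

test_that("the causal gene lands in the 90% credible set across seeds", {
  fx <- make_fixtures(tempfile("fmp"), "finemap_pair", seed = 73)
  panel <- fx$panel
  ld <- build_ld(panel)
  ms <- load_models(fx$weights, fx$intron_map)
  causal <- fx$truth$genes$gene_id[fx$truth$genes$causal]
  mods <- ms$models[paste(c("GENE0001", "GENE0002"), "breast", sep = "|")]
  ec <- expr_correlation(mods, ld, ridge = 0.1)
  hits <- 0
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    sums <- sim_gwas(panel, fx$truth, 30882, 115468, "direct", seed = 800 + s)
    z <- stats::setNames(sums$Z, sums$SNP)
    zg <- vapply(mods, function(m) .subset2(twas_zscore(m, z, ld), "Z"),
                 numeric(1))
    names(zg) <- vapply(mods, function(m) m$feature_id[1], character(1))
    fm <- credible_set(marginal_pips(zg, ec, k = 2))
    if (fm$IN_CREDIBLE_SET[fm$FEATURE == causal]) hits <- hits + 1
  }
  expect_gte(hits, 90)
})
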