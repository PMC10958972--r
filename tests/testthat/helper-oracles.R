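# Independent oracles used to freeze expected values; none of these call
# package internals.

# Dosage correlation implied by the Gaussian copula: both haplotypes are
# thresholded at qnorm(maf), so the dosage correlation equals the allele
# (Bernoulli) correlation, computed from the bivariate normal orthant
# probability by 1-D numerical integration.
dosage_cor_oracle <- function(rho, maf1, maf2) {
  t1 <- qnorm(maf1); t2 <- qnorm(maf2)
  p11 <- integrate(function(x)
    dnorm(x) * pnorm((t2 - rho * x) / sqrt(1 - rho^2)),
    lower = -Inf, upper = t1, rel.tol = 1e-10)$value
  (p11 - maf1 * maf2) / sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
}

# Plain high-precision evaluation of the Cauchy combination (no clipping or
# asymptotic branches).
acat_direct <- function(p, w = rep(1 / length(p), length(p))) {
  0.5 - atan(sum(w * tan((0.5 - p) * pi))) / pi
}

# Brute-force fine-mapping posterior over all 2^m causal configurations.
finemap_bruteforce <- function(z, Omega, pi0, v) {
  m <- length(z)
  configs <- lapply(0:(2^m - 1), function(code) which(bitwAnd(code, 2^(0:(m - 1))) > 0))
  logpost <- sapply(configs, function(C) {
    S <- Omega
    if (length(C)) {
      Oc <- Omega[, C, drop = FALSE]
      S <- S + v * Oc %*% t(Oc)
    }
    mvtnorm_ll <- -0.5 * (m * log(2 * pi) + determinant(S)$modulus +
                            drop(t(z) %*% solve(S, z)))
    mvtnorm_ll + length(C) * log(pi0) + (m - length(C)) * log(1 - pi0)
  })
  post <- exp(logpost - max(logpost))
  post <- post / sum(post)
  pip <- sapply(seq_len(m), function(i)
    sum(post[sapply(configs, function(C) i %in% C)]))
  list(pip = pip, null = post[1])
}
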