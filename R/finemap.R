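#' Predicted-expression correlation among features in a region
#'
#' The genetic correlation induced jointly by LD and the prediction-model
#' weights: `Omega_ij = (w_i' Gamma w_j) / (sigma_i sigma_j)` with
#' `sigma_i^2 = w_i' Gamma w_i`. An optional ridge is added to the diagonal
#' and the matrix is re-standardized to unit diagonal. Features with
#' non-positive predicted variance are excluded with a flag.
#'
#' @param models List of (feature, tissue) weight data.frames (as stored in
#'   a `model_set`), all resolvable in `ld`.
#' @param ld An `ld_block`.
#' @param ridge Diagonal ridge added before re-standardization (default 0.1).
#' @return An object of class `expr_corr`: list with `features` (ids),
#'   `Omega`, `sigma` and `excluded` (feature ids with sigma <= 0).
#' @export
expr_correlation <- function(models, ld, ridge = 0.1) {
  m <- length(models)
  ids <- vapply(models, function(d) d$feature_id[1], character(1))
  W <- matrix(0, length(ld$sigma), m, dimnames = list(ld$snps$SNP, ids))
  for (j in seq_len(m)) {
    d <- models[[j]]
    W[.ld_index(ld, d$SNP), j] <- d$weight
  }
  C <- crossprod(W, ld$Gamma %*% W)     # w_i' Gamma w_j
  sigma <- sqrt(pmax(diag(C), 0))
  bad <- sigma <= 0
  if (any(bad)) {
    .warnf("excluding %d feature(s) with non-positive predicted variance", sum(bad))
    C <- C[!bad, !bad, drop = FALSE]
    ids <- ids[!bad]
    sigma2 <- sigma[!bad]
  } else sigma2 <- sigma
  Omega <- C / outer(sigma2, sigma2)
  if (ridge > 0) {
    Omega <- Omega + diag(ridge, nrow(Omega))
    d <- sqrt(diag(Omega))
    Omega <- Omega / outer(d, d)
  }
  dimnames(Omega) <- list(ids, ids)
  structure(list(features = ids, Omega = Omega,
                 sigma = stats::setNames(sigma2, ids),
                 excluded = names(sigma)[bad]),
            class = "expr_corr")
}

#' Marginal posterior inclusion probabilities for features in a region
#'
#' Gene-level probabilistic fine-mapping: enumerates causal configurations
#' `C` of size at most `k` (including the empty, null configuration). Under
#' configuration `C` the TWAS z-score vector is modeled as
#' `z ~ N(0, Omega + v * Omega[, C] Omega[C, ]')` with `Omega` the
#' predicted-expression correlation; the configuration prior is
#' `pi0^|C| (1 - pi0)^(m - |C|)`. The marginal PIP of feature `i` is the
#' normalized posterior mass of configurations containing `i`. Features
#' with PIP at or above `pip_gate` are flagged candidate causal.
#'
#' @param z Named vector of TWAS z-scores for the region's features (one
#'   tissue, one approach).
#' @param ecorr An `expr_corr` for the same features.
#' @param pi0 Prior inclusion probability per feature (default 1e-3).
#' @param v Prior effect-size variance scalar on the z scale (default 30,
#'   roughly `N * sigma^2` for a well-powered study).
#' @param k Maximum number of simultaneously causal features (default 3,
#'   capped at the number of features).
#' @param pip_gate PIP threshold for the candidate-causal flag (default 0.9).
#' @return An object of class `finemap_result`: data.frame with FEATURE,
#'   Z, PIP, CANDIDATE_CAUSAL, plus attributes `null_posterior` and
#'   `config_posteriors`.
#' @export
marginal_pips <- function(z, ecorr, pi0 = 1e-3, v = 30, k = 3, pip_gate = 0.9) {
  if (pi0 <= 0 || pi0 >= 1) .stopf("pi0 must be in (0, 1)")
  ids <- ecorr$features
  zz <- z[match(ids, names(z))]
  if (anyNA(zz)) .stopf("z missing for feature(s): %s",
                        paste(ids[is.na(zz)], collapse = ", "))
  m <- length(ids)
  k <- min(k, m)
  Omega <- ecorr$Omega

  configs <- list(integer(0))
  for (s in seq_len(k))
    configs <- c(configs, utils::combn(m, s, simplify = FALSE))
  logpost <- vapply(configs, function(C) {
    S <- Omega
    if (length(C)) {
      Oc <- Omega[, C, drop = FALSE]
      S <- S + v * tcrossprod(Oc)
    }
    ll <- .ldmvnorm0(zz, S)
    if (isTRUE(attr(ll, "failed"))) return(-Inf)
    ll + length(C) * log(pi0) + (m - length(C)) * log(1 - pi0)
  }, numeric(1))
  if (any(!is.finite(logpost)))
    .warnf("skipped %d non-PSD configuration(s)", sum(!is.finite(logpost)))
  lse <- .logsumexp(logpost)
  post <- exp(logpost - lse)
  pip <- vapply(seq_len(m), function(i)
    sum(post[vapply(configs, function(C) i %in% C, logical(1))]), numeric(1))
  res <- data.frame(FEATURE = ids, Z = unname(zz), PIP = pip,
                    CANDIDATE_CAUSAL = pip >= pip_gate,
                    stringsAsFactors = FALSE)
  attr(res, "null_posterior") <- post[1]
  attr(res, "config_posteriors") <- post
  class(res) <- c("finemap_result", "data.frame")
  res
}

#' 90\% credible set of features for a region
#'
#' Ranks features by PIP (ties broken by feature id for determinism) and,
#' treating the null configuration as a competing item with mass equal to
#' its posterior, accumulates normalized posterior mass until it reaches
#' `rho`. In a null region the null configuration absorbs the mass and the
#' credible set is empty.
#'
#' @param records A `finemap_result` from [marginal_pips()].
#' @param rho Credible-set confidence level (default 0.9).
#' @return The input data.frame with an added IN_CREDIBLE_SET column.
#' @export
credible_set <- function(records, rho = 0.9) {
  pip <- records$PIP
  null_mass <- attr(records, "null_posterior")
  if (is.null(null_mass)) null_mass <- 0
  ord <- order(-pip, records$FEATURE)
  mass <- c(pip[ord], null_mass)
  is_null <- c(rep(FALSE, length(ord)), TRUE)
  rank_mass <- order(-mass)             # null competes at its posterior mass
  cum <- cumsum(mass[rank_mass]) / sum(mass)
  take <- rank_mass[seq_len(which(cum >= rho)[1])]
  in_set <- rep(FALSE, length(pip))
  in_set[ord[take[!is_null[take]]]] <- TRUE
  records$IN_CREDIBLE_SET <- in_set
  records
}

#' @export
print.finemap_result <- function(x, ...) {
  cat(sprintf("Fine-mapping: %d feature(s); null posterior %.3g\n",
              nrow(x), attr(x, "null_posterior")))
  print.data.frame(x, ...)
  invisible(x)
}
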