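#' Impute association z-scores at unobserved SNPs
#'
#' Gaussian conditional-mean imputation: under the model that the vector of
#' marginal z-scores in a region is `N(0, R)` with `R` the LD correlation
#' matrix, the posterior mean of unobserved z-scores given observed ones is
#' `z_t = R_to (R_oo + lambda I)^{-1} z_o`, with expected imputation
#' accuracy `r2pred = diag(R_to (R_oo + lambda I)^{-1} R_ot)`. Imputation is
#' performed within a single LD region, never across region boundaries.
#'
#' @param z_obs Named vector of observed z-scores; names are SNP ids present
#'   in `ld`.
#' @param ld An `ld_block` covering observed and target SNPs.
#' @param targets Character vector of SNP ids to impute (may include
#'   observed SNPs, which are passed through unchanged with `r2pred = 1`).
#' @param lambda Ridge added to `R_oo` (default 0.1, the usual convention
#'   for this estimator; the underlying model is silent on its value).
#' @param r2_floor Targets with `r2pred` below this are flagged low quality
#'   (default 0.6), not silently used.
#' @return A data.frame with SNP, Z, R2PRED, SOURCE (`observed`/`imputed`)
#'   and LOW_QUALITY flag.
#' @examples
#' panel <- sim_genotypes(500, ld_spec(1, 4, 0.8), seed = 1)
#' ld <- build_ld(panel)
#' zs <- stats::setNames(c(2, 1.5, 1), panel$map$SNP[1:3])
#' impute_zscores(zs, ld, panel$map$SNP)
#' @export
impute_zscores <- function(z_obs, ld, targets, lambda = 0.1, r2_floor = 0.6) {
  if (is.null(names(z_obs)) || !length(z_obs)) .stopf("z_obs must be a named, non-empty vector")
  oi <- .ld_index(ld, names(z_obs))
  ti <- .ld_index(ld, targets)

  out <- data.frame(SNP = targets, Z = NA_real_, R2PRED = NA_real_,
                    SOURCE = "imputed", stringsAsFactors = FALSE)
  obs_pos <- match(targets, names(z_obs))
  seen <- !is.na(obs_pos)
  out$Z[seen] <- z_obs[obs_pos[seen]]
  out$R2PRED[seen] <- 1
  out$SOURCE[seen] <- "observed"

  if (any(!seen)) {
    Roo <- ld$R[oi, oi, drop = FALSE]
    if (lambda > 0) Roo <- Roo + diag(lambda, nrow(Roo))
    Rto <- ld$R[ti[!seen], oi, drop = FALSE]
    W <- tryCatch(t(solve(Roo, t(Rto))), error = function(e)
      .stopf("observed-SNP correlation matrix is singular; use a positive lambda"))
    out$Z[!seen] <- drop(W %*% z_obs)
    out$R2PRED[!seen] <- pmin(rowSums(W * Rto), 1)
  }
  out$LOW_QUALITY <- out$R2PRED < r2_floor
  out
}
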