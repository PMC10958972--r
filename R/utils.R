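# Internal helpers shared across modules.

# Two-sided normal p-value from a z-score, guarded against p = 0 for the
# benefit of downstream Cauchy combination (which requires p in (0, 1]).
.z2p <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)
}

.is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Log-density of a zero-mean multivariate normal via Cholesky, escalating a
# diagonal ridge if the covariance is numerically non-PSD. Returns -Inf with
# attribute "failed" if no ridge within the schedule works.
.ldmvnorm0 <- function(z, S) {
  m <- length(z)
  for (ridge in c(0, 1e-10, 1e-8, 1e-6, 1e-4)) {
    Sr <- S
    if (ridge > 0) diag(Sr) <- diag(Sr) + ridge
    ch <- tryCatch(chol(Sr), error = function(e) NULL)
    if (!is.null(ch)) {
      u <- backsolve(ch, z, transpose = TRUE)
      return(-0.5 * (m * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(u^2)))
    }
  }
  structure(-Inf, failed = TRUE)
}

# AR(1) correlation matrix, used by the LD simulator and its tests.
.ar1_cor <- function(m, rho) {
  if (m == 1L) return(matrix(1, 1, 1))
  rho^abs(outer(seq_len(m), seq_len(m), "-"))
}

# log(sum(exp(x))) without overflow.
.logsumexp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}
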