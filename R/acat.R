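#' Aggregated Cauchy association test (ACAT) p-value combination
#'
#' Combines p-values via the Cauchy combination statistic
#' `T = sum_k w_k tan((0.5 - p_k) pi)` with combined p-value
#' `0.5 - arctan(T) / pi`. For `p_k < 1e-15` the term is replaced by its
#' asymptotic equivalent `w_k / (p_k pi)` to avoid overflow, and for very
#' large `T` the combined p-value is evaluated as `1 / (pi T)`; p-values of
#' exactly 1 are clipped to `1 - 1e-16` with a warning. The test is robust
#' to dependence among the component p-values.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @param weights Non-negative weights, normalized to sum to 1 (default
#'   equal weights `1/K`).
#' @return The combined p-value.
#' @examples
#' acat_pvalue(c(0.01, 0.5))
#' acat_pvalue(rep(0.2, 11))  # fixed point: 0.2
#' @export
acat_pvalue <- function(p, weights = NULL) {
  if (!length(p) || anyNA(p)) .stopf("p must be a non-empty vector without NA")
  if (any(p <= 0) || any(p > 1)) .stopf("p-values must lie in (0, 1]")
  if (is.null(weights)) weights <- rep(1 / length(p), length(p))
  if (length(weights) != length(p) || any(weights < 0) || anyNA(weights))
    .stopf("weights must be non-negative and match length(p)")
  sw <- sum(weights)
  if (sw <= 0) .stopf("weights must not all be zero")
  if (abs(sw - 1) > 1e-12) weights <- weights / sw
  if (any(p == 1)) {
    .warnf("p-value(s) of 1 clipped to 1 - 1e-16")
    p <- pmin(p, 1 - 1e-16)
  }
  tiny <- p < 1e-15
  terms <- numeric(length(p))
  terms[!tiny] <- weights[!tiny] * tanpi(0.5 - p[!tiny])
  terms[tiny] <- weights[tiny] / (p[tiny] * pi)
  T_acat <- sum(terms)
  if (T_acat > 1e15) return(1 / (pi * T_acat))
  max(0.5 - atan(T_acat) / pi, .Machine$double.xmin)
}

#' Gene-level splicing p-value within one tissue
#'
#' First step of the two-step splicing aggregation: equal-weight ACAT over
#' the testable intron-excision TWAS p-values of one gene in one tissue.
#'
#' @param intron_results Data.frame of intron-level TWAS results for a
#'   single gene and tissue (columns P and FLAGS as produced by
#'   [run_tissue_twas()]).
#' @return The per-tissue gene p-value, or `NA_real_` when no intron is
#'   testable (the gene is untestable in that tissue; the NA propagates as
#'   an absent tissue in the multi-tissue step).
#' @export
splice_gene_pvalue <- function(intron_results) {
  ok <- is.finite(intron_results$P) & intron_results$FLAGS != "untestable"
  if (!any(ok)) return(NA_real_)
  acat_pvalue(intron_results$P[ok])
}

#' Multi-tissue joint p-value for one gene
#'
#' Second aggregation step: equal-weight ACAT over the K tissues in which
#' the gene has a testable p-value (`w_k = 1/K`; for a full 11-tissue roster
#' this is the 1/11 weighting, and for genes modeled in fewer tissues the
#' weights remain equal over the tissues with models). A sample-size
#' weighted variant (`w_k` proportional to `sqrt(n_k)`) is available for
#' sensitivity analyses.
#'
#' @param tissue_p Named numeric vector of per-tissue p-values for one gene
#'   (NA for untestable tissues; these are excluded from K).
#' @param approach `"expression"` or `"splicing"` (recorded, not used in the
#'   arithmetic).
#' @param gene Gene id to record.
#' @param tissue_n Optional named vector of per-tissue prediction-model
#'   sample sizes; when supplied with `weight_mode = "sqrt_n"`, weights are
#'   proportional to `sqrt(n_k)`.
#' @param weight_mode `"equal"` (default) or `"sqrt_n"`.
#' @return A one-row data.frame: GENE, APPROACH, JOINT_P, N_TISSUES,
#'   BREAST_P (the `breast` tissue's p if present, else NA), MIN_TISSUE
#'   (tissue attaining the minimum p).
#' @export
multi_tissue_pvalue <- function(tissue_p, approach = c("expression", "splicing"),
                                gene = NA_character_, tissue_n = NULL,
                                weight_mode = c("equal", "sqrt_n")) {
  approach <- match.arg(approach)
  weight_mode <- match.arg(weight_mode)
  ok <- is.finite(tissue_p)
  if (!any(ok)) .stopf("no testable tissue p-value for gene %s", gene)
  p <- tissue_p[ok]
  w <- if (weight_mode == "sqrt_n") {
    if (is.null(tissue_n)) .stopf("tissue_n required for sqrt_n weighting")
    sqrt(tissue_n[names(p)])
  } else rep(1 / length(p), length(p))
  joint <- acat_pvalue(p, w)
  data.frame(GENE = gene, APPROACH = approach, JOINT_P = joint,
             N_TISSUES = length(p),
             BREAST_P = if ("breast" %in% names(p)) unname(p["breast"]) else NA_real_,
             MIN_TISSUE = names(p)[which.min(p)],
             stringsAsFactors = FALSE)
}

#' Bonferroni significance threshold
#'
#' `alpha / n` over the number of features tested by an approach, with a
#' two-significant-figure display form matching how such thresholds are
#' conventionally reported (0.05 over 19,288 genes prints as 2.6e-06).
#'
#' @param n_tests Number of tests (>= 1).
#' @param alpha Family-wise error rate (default 0.05).
#' @return List with `threshold` (exact) and `display` (2 significant
#'   figures).
#' @examples
#' bonferroni_threshold(19288)$display
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (!.is_count(n_tests)) .stopf("n_tests must be a positive integer")
  if (alpha <= 0 || alpha >= 1) .stopf("alpha must be in (0, 1)")
  thr <- alpha / n_tests
  list(threshold = thr, display = signif(thr, 2))
}
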