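#' Load and index per-tissue SNP-weight prediction models
#'
#' Reads a long-format weight table (one row per model SNP) for gene
#' expression and intron-excision features across tissues, plus the
#' intron-to-gene map, and builds an indexed registry. Weights follow the
#' "effect allele adds weight" convention: harmonization flips GWAS
#' z-scores, never model weights.
#'
#' @param weights A data.frame with columns feature_id, feature_type
#'   (`gene`/`intron`), gene_id, tissue, SNP, A1, A2, weight - or a path to
#'   such a TSV.
#' @param intron_map A data.frame with columns intron_id, gene_id, or a path
#'   to such a TSV. May be `NULL` when no intron features are present.
#' @return An object of class `model_set`: list with `models` (list keyed
#'   `"<feature>|<tissue>"`, each holding the feature's weight data.frame),
#'   `features` (per-feature metadata), `tissues` (roster), `gene_index`
#'   (gene -> intron ids) and `variants` (reference orientation table of all
#'   model SNPs).
#' @export
load_models <- function(weights, intron_map = NULL) {
  if (is.character(weights)) weights <- utils::read.delim(weights, stringsAsFactors = FALSE)
  if (is.character(intron_map)) intron_map <- utils::read.delim(intron_map, stringsAsFactors = FALSE)
  need <- c("feature_id", "feature_type", "gene_id", "tissue", "SNP", "A1", "A2", "weight")
  miss <- setdiff(need, names(weights))
  if (length(miss)) .stopf("weight table missing columns: %s", paste(miss, collapse = ", "))
  if (!all(weights$feature_type %in% c("gene", "intron")))
    .stopf("feature_type must be 'gene' or 'intron'")
  bad_gene <- weights$feature_type == "intron" &
    (is.na(weights$gene_id) | weights$gene_id == "")
  if (any(bad_gene)) .stopf("intron feature(s) without a parent gene id")
  zero <- weights$weight == 0
  if (any(zero)) {
    .warnf("dropping %d zero-weight row(s)", sum(zero))
    weights <- weights[!zero, , drop = FALSE]
  }

  # deterministic, input-order-independent indexing
  weights <- weights[order(weights$feature_id, weights$tissue, weights$SNP), , drop = FALSE]
  key <- paste(weights$feature_id, weights$tissue, sep = "|")
  if (anyDuplicated(paste(key, weights$SNP)))
    .stopf("duplicate SNP within a (feature, tissue) model")
  models <- split(weights, factor(key, levels = unique(key)))
  models <- lapply(models, function(d) { rownames(d) <- NULL; d })

  fmeta <- weights[!duplicated(weights$feature_id),
                   c("feature_id", "feature_type", "gene_id"), drop = FALSE]
  rownames(fmeta) <- NULL
  tissues <- sort(unique(weights$tissue))
  gene_index <- if (is.null(intron_map)) list() else
    split(intron_map$intron_id, intron_map$gene_id)
  variants <- weights[!duplicated(weights$SNP), c("SNP", "A1", "A2"), drop = FALSE]
  rownames(variants) <- NULL
  structure(list(models = models, features = fmeta, tissues = tissues,
                 gene_index = gene_index, variants = variants),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  genes <- x$features$feature_id[x$features$feature_type == "gene"]
  introns <- x$features$feature_id[x$features$feature_type == "intron"]
  cat(sprintf("Model registry: %d gene(s), %d intron feature(s), %d tissue(s), %d (feature, tissue) models\n",
              length(genes), length(introns), length(x$tissues), length(x$models)))
  cat(sprintf("  genes with any model (union over tissues): %d\n",
              length(unique(x$features$gene_id))))
  invisible(x)
}

#' Count genes tested per tissue and in the union over tissues
#'
#' The union over tissues is the Bonferroni universe for the multi-tissue
#' test; single-tissue counts support breast-only analyses.
#'
#' @param model_set A `model_set`.
#' @param feature_type `"gene"` or `"intron"` features to count; gene-level
#'   counts for introns are of distinct parent genes.
#' @return List with `per_tissue` (named integer vector) and `union` count.
#' @export
count_features <- function(model_set, feature_type = "gene") {
  keys <- names(model_set$models)
  ft <- model_set$features
  per <- integer(0)
  genes_by_tissue <- list()
  for (tis in model_set$tissues) {
    feats <- sub("\\|.*$", "", keys[endsWith(keys, paste0("|", tis))])
    feats <- feats[feats %in% ft$feature_id[ft$feature_type == feature_type]]
    g <- unique(ft$gene_id[match(feats, ft$feature_id)])
    genes_by_tissue[[tis]] <- g
    per[tis] <- length(g)
  }
  list(per_tissue = per, union = length(unique(unlist(genes_by_tissue))))
}

#' Fraction of model SNPs with a usable GWAS z-score
#'
#' @param model_set A `model_set`.
#' @param z Named z-score vector (e.g. the `z` element of a
#'   `harmonized_set`), or a `harmonized_set`.
#' @return A data.frame with feature_id, tissue, n_model, n_usable,
#'   coverage in `[0, 1]`, and a list-column `missing` of absent SNP ids.
#' @export
model_coverage <- function(model_set, z) {
  if (inherits(z, "harmonized_set")) z <- z$z
  have <- names(z)[is.finite(z)]
  ml <- model_set$models
  n_model <- vapply(ml, nrow, integer(1))
  snps <- unlist(lapply(ml, `[[`, "SNP"), use.names = FALSE)
  usable <- snps %in% have
  grp <- rep(seq_along(ml), n_model)
  n_usable <- as.integer(rowsum(as.integer(usable), grp, reorder = FALSE))
  res <- data.frame(
    feature_id = vapply(ml, function(d) d$feature_id[1], character(1)),
    tissue = vapply(ml, function(d) d$tissue[1], character(1)),
    n_model = n_model, n_usable = n_usable, coverage = n_usable / n_model,
    stringsAsFactors = FALSE)
  miss <- rep(list(character(0)), length(ml))
  if (any(!usable)) {
    ms <- split(snps[!usable], grp[!usable])
    miss[as.integer(names(ms))] <- ms
  }
  res$missing <- miss
  rownames(res) <- NULL
  res
}
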