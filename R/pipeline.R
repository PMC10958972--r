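#' Assemble and validate a pipeline configuration
#'
#' Inputs may be given as file paths (the fixture-bundle formats written by
#' [make_fixtures()]) or as in-memory objects (a summary-statistics
#' data.frame, a weight table, a named list of `ld_block`s), which is
#' convenient for simulation sweeps. A YAML file of the same fields is
#' accepted via `yaml_path` when the `yaml` package is available.
#'
#' @param sumstats Path to a sumstats TSV or a data.frame.
#' @param weights Path to a weight-table TSV or a data.frame.
#' @param intron_map Path or data.frame (may be `NULL`).
#' @param ld Directory containing `*.ld.tsv` / `*.vars.tsv` block files, or
#'   a named list of `ld_block`s.
#' @param index_snps Path or data.frame (SNP, CHR, POS, ...); may be `NULL`
#'   or empty.
#' @param outdir Output directory for stage artifacts, or `NULL` to skip
#'   writing.
#' @param alpha Family-wise error rate for the Bonferroni gate (default 0.05).
#' @param window Conditioning window in bp (default 2e6).
#' @param weight_mode ACAT tissue weighting, `"equal"` or `"sqrt_n"`.
#' @param impute_lambda,r2_floor Imputation ridge and quality floor.
#' @param finemap_pi0,finemap_v,finemap_k,finemap_ridge Fine-mapping prior
#'   inclusion probability, prior variance scalar, maximum causal features
#'   and expression-correlation ridge.
#' @param run_conditional,run_finemap Stage switches.
#' @param seed Integer seed recorded in the manifest (the analysis itself
#'   is deterministic).
#' @param yaml_path Optional YAML file whose fields override the defaults.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sumstats, weights, intron_map = NULL, ld,
                            index_snps = NULL, outdir = NULL, alpha = 0.05,
                            window = 2e6, weight_mode = "equal",
                            impute_lambda = 0.1, r2_floor = 0.6,
                            finemap_pi0 = 1e-3, finemap_v = 30,
                            finemap_k = 3, finemap_ridge = 0.1,
                            run_conditional = TRUE, run_finemap = TRUE,
                            seed = 1, yaml_path = NULL) {
  cfg <- list(sumstats = sumstats, weights = weights, intron_map = intron_map,
              ld = ld, index_snps = index_snps, outdir = outdir,
              alpha = alpha, window = window, weight_mode = weight_mode,
              impute_lambda = impute_lambda, r2_floor = r2_floor,
              finemap_pi0 = finemap_pi0, finemap_v = finemap_v,
              finemap_k = finemap_k, finemap_ridge = finemap_ridge,
              run_conditional = run_conditional, run_finemap = run_finemap,
              seed = seed)
  if (!is.null(yaml_path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      .stopf("the yaml package is required for yaml_path")
    over <- yaml::read_yaml(yaml_path)
    cfg[names(over)] <- over
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) .stopf("alpha must be in (0, 1)")
  for (f in c("sumstats", "weights", "intron_map", "index_snps"))
    if (is.character(cfg[[f]]) && !file.exists(cfg[[f]]))
      .stopf("%s file not found: %s", f, cfg[[f]])
  if (is.character(cfg$ld) && !dir.exists(cfg$ld))
    .stopf("LD directory not found: %s", cfg$ld)
  structure(cfg, class = "pipeline_config")
}

# Load the LD blocks of a config into a named list of ld_block objects.
.load_ld <- function(ld) {
  if (is.list(ld) && !is.character(ld)) {
    if (inherits(ld, "ld_block")) return(list(region_1 = ld))
    return(ld)
  }
  sidecars <- sort(list.files(ld, pattern = "\\.vars\\.tsv$", full.names = TRUE))
  if (!length(sidecars)) .stopf("no *.vars.tsv LD sidecars in %s", ld)
  prefixes <- sub("\\.vars\\.tsv$", "", sidecars)
  blocks <- lapply(prefixes, read_ld)
  names(blocks) <- basename(prefixes)
  blocks
}

.read_or_pass <- function(x, reader = function(p) utils::read.delim(p, stringsAsFactors = FALSE)) {
  if (is.character(x)) reader(x) else x
}

#' Run the full TWAS pipeline
#'
#' Orchestrates harmonization, z-score imputation at model SNPs missing
#' from the GWAS, per-tissue expression and splicing TWAS, the two-step
#' ACAT aggregation, the Bonferroni gate (separate universes for the
#' expression and splicing approaches; a gene is "identified" when it is
#' significant by either), conditional TWAS against GWAS index variants,
#' index-variant mediation, and per-region gene-level fine-mapping
#' (expression and splicing features in separate runs). Per-feature
#' failures are logged and skipped; only missing stage inputs are fatal.
#'
#' @param config A `pipeline_config`.
#' @return An object of class `twas_report`: list with `report` (the
#'   gene-level table), `thresholds`, `tissue_results`, `gene_results`,
#'   `conditioned`, `mediation`, `finemap`, `coverage`, `imputed` and the
#'   `config`. When `config$outdir` is set, all stage tables are written as
#'   TSV plus a JSON manifest.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) .stopf("config must be a pipeline_config")
  set.seed(config$seed)
  sums <- .read_or_pass(config$sumstats, read_sumstats)
  weights <- .read_or_pass(config$weights)
  intron_map <- if (is.null(config$intron_map)) NULL else .read_or_pass(config$intron_map)
  index_df <- if (is.null(config$index_snps)) NULL else .read_or_pass(config$index_snps)
  ld_blocks <- .load_ld(config$ld)
  model_set <- load_models(weights, intron_map)

  # reference orientation: the LD panel's variant sidecars
  ref <- do.call(rbind, lapply(ld_blocks, function(b)
    b$snps[, c("SNP", "CHR", "POS", "A1", "A2")]))
  ref <- ref[!duplicated(ref$SNP), , drop = FALSE]
  harm <- harmonize(sums, ref)

  snp_region <- stats::setNames(
    rep(names(ld_blocks), vapply(ld_blocks, function(b) nrow(b$snps), integer(1))),
    unlist(lapply(ld_blocks, function(b) b$snps$SNP), use.names = FALSE))
  feat_snp1 <- vapply(model_set$models, function(d) d$SNP[1], character(1))
  region_of <- stats::setNames(snp_region[feat_snp1],
                               vapply(model_set$models, function(d) d$feature_id[1], character(1)))
  region_of <- region_of[!duplicated(names(region_of))]

  # impute missing model-SNP z-scores per region; low-quality imputations
  # are flagged and withheld from the TWAS
  z <- harm$z
  model_snps <- unique(weights$SNP)
  missing <- setdiff(model_snps, names(z))
  imputed <- NULL
  if (length(missing)) {
    imp_rows <- list()
    for (reg in unique(snp_region[missing])) {
      reg_snps <- names(snp_region)[snp_region == reg]
      obs <- z[names(z) %in% reg_snps]
      targ <- intersect(missing, reg_snps)
      if (!length(obs) || !length(targ)) next
      imp <- impute_zscores(obs, ld_blocks[[reg]], targ,
                            lambda = config$impute_lambda,
                            r2_floor = config$r2_floor)
      imp$REGION <- reg
      imp_rows[[reg]] <- imp
    }
    imputed <- do.call(rbind, imp_rows)
    if (!is.null(imputed)) {
      rownames(imputed) <- NULL
      good <- imputed$SOURCE == "imputed" & !imputed$LOW_QUALITY
      z <- c(z, stats::setNames(imputed$Z[good], imputed$SNP[good]))
    }
  }

  coverage <- model_coverage(model_set, z)

  tissue_results <- do.call(rbind, lapply(model_set$tissues, function(tis)
    run_tissue_twas(model_set, z, ld_blocks, tis, region_of = region_of)))
  rownames(tissue_results) <- NULL

  gene_results <- aggregate_gene_pvalues(tissue_results, model_set,
                                         weight_mode = config$weight_mode)

  n_expr <- length(unique(gene_results$GENE[gene_results$APPROACH == "expression"]))
  n_spl <- length(unique(gene_results$GENE[gene_results$APPROACH == "splicing"]))
  thresholds <- list(
    expression = if (n_expr) bonferroni_threshold(n_expr, config$alpha) else NULL,
    splicing = if (n_spl) bonferroni_threshold(n_spl, config$alpha) else NULL)

  conditioned <- NULL
  mediation <- NULL
  have_index <- !is.null(index_df) && nrow(index_df) > 0
  if (config$run_conditional && have_index) {
    conditioned <- conditional_twas(model_set, z, index_df, ld_blocks,
                                    region_of = region_of, window = config$window)
    med_rows <- list()
    for (i in seq_len(nrow(index_df))) {
      snp <- index_df$SNP[i]
      reg <- snp_region[snp]
      rec <- harm$records[harm$records$SNP == snp, , drop = FALSE]
      if (is.na(reg) || nrow(rec) == 0) next
      ld <- ld_blocks[[reg]]
      adjusting <- intersect(model_snps, ld$snps$SNP)
      adjusting <- adjusting[adjusting %in% names(z)]
      if (!length(adjusting)) next
      med_rows[[snp]] <- proportion_mediated(rec[1, ], adjusting, ld, z)
    }
    mediation <- do.call(rbind, med_rows)
    if (!is.null(mediation)) rownames(mediation) <- NULL
  }

  finemap <- NULL
  if (config$run_finemap) {
    fm_rows <- list()
    for (reg in unique(region_of)) {
      feats_in_reg <- names(region_of)[region_of == reg]
      for (tis in model_set$tissues) {
        for (ftype in c("gene", "intron")) {
          ids <- intersect(feats_in_reg,
                           model_set$features$feature_id[model_set$features$feature_type == ftype])
          sub <- tissue_results[tissue_results$tissue == tis &
                                  tissue_results$feature_id %in% ids &
                                  tissue_results$FLAGS != "untestable", , drop = FALSE]
          if (!nrow(sub)) next
          mods <- model_set$models[paste(sub$feature_id, tis, sep = "|")]
          ec <- expr_correlation(mods, ld_blocks[[reg]], ridge = config$finemap_ridge)
          if (!length(ec$features)) next
          zz <- stats::setNames(sub$Z, sub$feature_id)
          fm <- marginal_pips(zz, ec, pi0 = config$finemap_pi0,
                              v = config$finemap_v, k = config$finemap_k)
          fm <- credible_set(fm)
          fm_rows[[length(fm_rows) + 1L]] <- data.frame(
            REGION = reg, TISSUE = tis, FEATURE = fm$FEATURE, TYPE = ftype,
            GENE = model_set$features$gene_id[match(fm$FEATURE, model_set$features$feature_id)],
            PIP = fm$PIP, IN_CREDIBLE_SET = fm$IN_CREDIBLE_SET,
            CANDIDATE_CAUSAL = fm$CANDIDATE_CAUSAL,
            NULL_POSTERIOR = attr(fm, "null_posterior"),
            stringsAsFactors = FALSE)
        }
      }
    }
    finemap <- do.call(rbind, fm_rows)
    if (!is.null(finemap)) rownames(finemap) <- NULL
  }

  report <- .gene_report(gene_results, thresholds, conditioned, finemap, index_df)

  out <- structure(list(report = report, thresholds = thresholds,
                        tissue_results = tissue_results,
                        gene_results = gene_results, conditioned = conditioned,
                        mediation = mediation, finemap = finemap,
                        coverage = coverage, imputed = imputed,
                        harmonized = harm, config = config),
                   class = "twas_report")
  if (!is.null(config$outdir)) .write_artifacts(out, config$outdir)
  out
}

# Gene-level report in the shape of the published summary tables: joint and
# breast-only p-values per approach, significance flags, conditioned
# p-values and maximum PIPs.
.gene_report <- function(gene_results, thresholds, conditioned, finemap,
                         index_df) {
  genes <- sort(unique(gene_results$GENE))
  pick <- function(df, appr, col) {
    if (is.null(df)) return(rep(NA_real_, length(genes)))
    sub <- df[df$APPROACH == appr, , drop = FALSE]
    sub[[col]][match(genes, sub$GENE)]
  }
  thr_e <- if (!is.null(thresholds$expression)) thresholds$expression$threshold else NA_real_
  thr_s <- if (!is.null(thresholds$splicing)) thresholds$splicing$threshold else NA_real_
  ep <- pick(gene_results, "expression", "JOINT_P")
  sp <- pick(gene_results, "splicing", "JOINT_P")
  esig <- !is.na(ep) & !is.na(thr_e) & ep < thr_e
  ssig <- !is.na(sp) & !is.na(thr_s) & sp < thr_s
  cond <- if (is.null(conditioned)) NULL else conditioned$genes
  mpe <- mps <- rep(NA_real_, length(genes))
  if (!is.null(finemap)) {
    fe <- finemap[finemap$TYPE == "gene", , drop = FALSE]
    fs <- finemap[finemap$TYPE == "intron", , drop = FALSE]
    if (nrow(fe)) {
      mx <- tapply(fe$PIP, fe$GENE, max)
      mpe <- as.numeric(mx[match(genes, names(mx))])
    }
    if (nrow(fs)) {
      mx <- tapply(fs$PIP, fs$GENE, max)
      mps <- as.numeric(mx[match(genes, names(mx))])
    }
  }
  data.frame(GENE = genes, EXPR_P = ep, SPLICE_P = sp,
             EXPR_BREAST_P = pick(gene_results, "expression", "BREAST_P"),
             SPLICE_BREAST_P = pick(gene_results, "splicing", "BREAST_P"),
             EXPR_SIG = esig, SPLICE_SIG = ssig,
             IDENTIFIED = esig | ssig,
             COND_EXPR_P = pick(cond, "expression", "JOINT_P"),
             COND_SPLICE_P = pick(cond, "splicing", "JOINT_P"),
             MAX_PIP_EXPR = mpe, MAX_PIP_SPLICE = mps,
             stringsAsFactors = FALSE)
}

.write_artifacts <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (is.null(df)) return(NULL)
    path <- file.path(outdir, paste0(name, ".tsv"))
    cols <- !vapply(df, is.list, logical(1))
    utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    basename(path)
  }
  files <- c(wr(out$report, "gene_report"),
             wr(out$tissue_results, "tissue_twas"),
             wr(out$gene_results, "gene_acat"),
             wr(if (!is.null(out$conditioned)) out$conditioned$genes, "gene_acat_conditioned"),
             wr(out$mediation, "mediation"),
             wr(out$finemap, "finemap"),
             wr(out$coverage, "model_coverage"),
             wr(out$imputed, "imputed_z"))
  manifest <- list(
    seed = out$config$seed, alpha = out$config$alpha,
    thresholds = lapply(out$thresholds, function(t) if (is.null(t)) NULL else t$threshold),
    n_genes_identified = sum(out$report$IDENTIFIED),
    files = files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.twas_report <- function(x, ...) {
  cat("Multi-tissue TWAS report\n")
  cat(sprintf("  genes (expression universe): %d  threshold %s\n",
              length(unique(x$gene_results$GENE[x$gene_results$APPROACH == "expression"])),
              if (!is.null(x$thresholds$expression))
                format(x$thresholds$expression$display) else "-"))
  cat(sprintf("  genes (splicing universe):   %d  threshold %s\n",
              length(unique(x$gene_results$GENE[x$gene_results$APPROACH == "splicing"])),
              if (!is.null(x$thresholds$splicing))
                format(x$thresholds$splicing$display) else "-"))
  cat(sprintf("  genes identified (either approach): %d\n", sum(x$report$IDENTIFIED)))
  if (!is.null(x$mediation))
    cat(sprintf("  index variants mediated: %d of %d\n",
                sum(x$mediation$MEDIATED), nrow(x$mediation)))
  invisible(x)
}

#' @export
summary.twas_report <- function(object, ...) {
  print(object)
  sig <- object$report[object$report$IDENTIFIED, , drop = FALSE]
  if (nrow(sig)) {
    cat("\nIdentified genes:\n")
    print.data.frame(sig[, c("GENE", "EXPR_P", "SPLICE_P", "MAX_PIP_EXPR",
                             "MAX_PIP_SPLICE")], row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' Overlap of identified genes between two subtype reports
#'
#' @param report1,report2 `twas_report` objects (or their `report` tables)
#'   from the same gene universe.
#' @param labels Length-2 character labels for the two subtypes.
#' @return List with per-subtype totals, `shared` count, per-subtype
#'   `unique` counts and the gene-id sets.
#' @export
subtype_overlap <- function(report1, report2, labels = c("ERpos", "ERneg")) {
  tab <- function(r) if (inherits(r, "twas_report")) r$report else r
  g1 <- tab(report1); g2 <- tab(report2)
  s1 <- g1$GENE[g1$IDENTIFIED]
  s2 <- g2$GENE[g2$IDENTIFIED]
  both <- intersect(s1, s2)
  res <- list(total = stats::setNames(c(length(s1), length(s2)), labels),
              shared = length(both),
              unique = stats::setNames(c(length(setdiff(s1, s2)),
                                         length(setdiff(s2, s1))), labels),
              genes = list(both = sort(both),
                           only1 = sort(setdiff(s1, s2)),
                           only2 = sort(setdiff(s2, s1))))
  names(res$genes)[2:3] <- paste0("only_", labels)
  res
}
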