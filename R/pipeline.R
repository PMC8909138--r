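#' Default pipeline configuration
#'
#' Aggregates the stage parameters with their standard values: top-fraction
#' 0.02, gene filters mean TPM > 0.2 and >= 30 expressing cells, DEG cutoffs
#' Bonferroni 0.005 and |log2FC| > 2, 1000 variable genes, 100 deconvolution
#' permutations, GSEA FDR 0.05.
#'
#' @param ... Overrides of any default entry.
#' @return A named list of class `PipelineConfig`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(fraction = 0.02, mean_tpm_min = 0.2, min_cells = 30,
              deg_alpha = 0.005, deg_lfc = 2, n_variable_genes = 1000,
              deconv_perms = 100, gsea_fdr = 0.05, gsea_perms = 1000,
              ssgsea_alpha = 0.25, module_bins = 25, module_ctrl = 100,
              seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config entries: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("PipelineConfig", "list"))
}

manifest_write <- function(out_dir, params, files) {
  hashes <- tools::md5sum(file.path(out_dir, files))
  names(hashes) <- files
  jsonlite::write_json(list(parameters = params,
                            files = as.list(hashes)),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Run the single-cell arm of the pipeline
#'
#' From a TPM matrix and the lipid/G1S/G2M gene sets: filters genes, scores
#' every cell, calls the SCC, FCC and marker-high groups (top fraction with
#' MMR report), computes the overlap decomposition and the multi-marker
#' combination population, runs SCC-vs-each-group differential expression on
#' private cells, selects variable genes, embeds cells by PCA and clusters
#' the groups. All artifacts are written under `out_dir` together with a
#' manifest recording parameters and content hashes.
#'
#' @param m An `ExpressionMatrix` (TPM).
#' @param gene_sets A `GeneSetCollection` containing sets named
#'   "lipid_metabolism", "G1S" and "G2M".
#' @param markers Marker gene names to call marker-high groups from.
#' @param out_dir Output directory (created if missing).
#' @param config A [pipeline_config()].
#' @return Invisible list of in-memory results (scores, groups, overlap, DEG
#'   tables, PCA coordinates, cluster tree).
#' @export
run_single_cell <- function(m, gene_sets, markers, out_dir,
                            config = pipeline_config()) {
  stopifnot(inherits(m, "ExpressionMatrix"),
            inherits(gene_sets, "GeneSetCollection"))
  need <- c("lipid_metabolism", "G1S", "G2M")
  miss <- setdiff(need, names(gene_sets))
  if (length(miss)) stop("gene_sets lacks: ", paste(miss, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  mf <- filter_genes(m, config$mean_tpm_min, config$min_cells)
  lm <- log2_tpm1(mf)

  lipid <- ssgsea_score(mf, gene_sets[["lipid_metabolism"]],
                        alpha = config$ssgsea_alpha)
  g1s <- tirosh_module_score(lm, gene_sets[["G1S"]], config$module_bins,
                             config$module_ctrl, seed = config$seed)
  g2m <- tirosh_module_score(lm, gene_sets[["G2M"]], config$module_bins,
                             config$module_ctrl, seed = config$seed + 1L)
  ccs <- cell_cycle_score(g1s, g2m)

  scc <- top_fraction(lipid, config$fraction, name = "SCC",
                      kind = "signature")
  fcc <- top_fraction(ccs, config$fraction, name = "FCC", kind = "cycle")
  mgroups <- lapply(markers, function(mk)
    marker_group(mf, mk, config$fraction))
  names(mgroups) <- markers
  groups <- c(list(SCC = scc, FCC = fcc), mgroups)

  # MMR homogeneity is defined on strictly positive ranking scores, i.e. the
  # marker-expression groups; signature/cycle scores can be <= 0.
  mmr <- mmr_check(mgroups)
  ov <- compute_overlap(groups)
  combo <- combo_csc(mgroups)

  scc_priv <- private_cells(groups, "SCC")
  deg <- lapply(setdiff(names(groups), "SCC"), function(g) {
    other_priv <- private_cells(groups, g)
    deg_filter(moderated_t(lm, scc_priv, other_priv),
               config$deg_alpha, config$deg_lfc)
  })
  names(deg) <- paste0("SCC_vs_", setdiff(names(groups), "SCC"))

  hvg <- top_variable_genes(lm, min(config$n_variable_genes, nrow(lm$values)))
  grouped_cells <- unique(unlist(lapply(groups, `[[`, "cell_ids")))
  sub <- expression_matrix(lm$values[, grouped_cells, drop = FALSE],
                           "LOG2_TPM1")
  pca <- pca_embed(sub, genes = hvg, k = 3)
  tree <- hcluster(t(vapply(groups, function(g)
    rowMeans(lm$values[hvg, g$cell_ids, drop = FALSE]),
    numeric(length(hvg)))), linkage = "average")

  write_scores(lipid, file.path(out_dir, "score_lipid.tsv"))
  write_scores(ccs, file.path(out_dir, "score_ccs.tsv"))
  write_groups(groups, file.path(out_dir, "groups.tsv"))
  write_overlap_json(ov, file.path(out_dir, "overlap.json"))
  utils::write.table(mmr, file.path(out_dir, "mmr_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(deg))
    write_deg_table(deg[[nm]], file.path(out_dir, paste0("deg_", nm, ".tsv")))
  utils::write.table(data.frame(cell_id = rownames(pca), pca),
                     file.path(out_dir, "pca_coords.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(tree_newick(tree), file.path(out_dir, "group_tree.nwk"))

  files <- c("score_lipid.tsv", "score_ccs.tsv", "groups.tsv",
             "overlap.json", "mmr_report.tsv",
             paste0("deg_", names(deg), ".tsv"), "pca_coords.tsv",
             "group_tree.nwk")
  manifest_write(out_dir, unclass(config), files)
  invisible(list(scores = list(lipid = lipid, g1s = g1s, g2m = g2m,
                               ccs = ccs),
                 groups = groups, combo = combo, mmr = mmr, overlap = ov,
                 deg = deg, pca = pca, tree = tree))
}

#' Run the bulk arm of the pipeline
#'
#' Builds an SCC/FCC signature matrix from the called single-cell groups,
#' deconvolves the bulk cohort in absolute mode, stratifies samples by mean
#' score cutoff, and compares overall survival between strata by
#' Kaplan-Meier and log-rank.
#'
#' @param m Single-cell `ExpressionMatrix` (TPM) containing the group
#'   members.
#' @param groups List of two disjoint `CellGroup`s (SCC and FCC).
#' @param bulk Bulk `ExpressionMatrix` (genes x samples, TPM).
#' @param clinical A `SurvivalRecords` data.frame covering the bulk samples.
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return Invisible list with the signature, deconvolution table, strata,
#'   KM curves and log-rank result.
#' @export
run_bulk <- function(m, groups, bulk, clinical, out_dir,
                     config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sig <- build_signature(m, groups)
  dec <- deconvolve(sig, bulk, n_perm = config$deconv_perms,
                    seed = config$seed)
  pop1 <- sig$populations[1]
  scores <- stats::setNames(dec[[pop1]], dec$sample)
  strata <- stratify_by_score(scores, rule = "mean")
  rec <- clinical[match(names(strata), clinical$sample_id), ]
  rec$stratum <- unname(strata)
  rec <- rec[!is.na(rec$sample_id), ]
  lr <- logrank_test(rec)
  km <- lapply(split(rec, rec$stratum), km_estimate)

  write_signature(sig, file.path(out_dir, "signature_matrix.tsv"))
  utils::write.table(dec, file.path(out_dir, "deconvolution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(strata), stratum = strata),
                     file.path(out_dir, "strata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (s in names(km))
    write_km_curve(km[[s]], file.path(out_dir, paste0("km_", s, ".tsv")))
  jsonlite::write_json(list(chi2 = lr$chi2, p = lr$p),
                       file.path(out_dir, "logrank.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c("signature_matrix.tsv", "deconvolution.tsv", "strata.tsv",
             paste0("km_", names(km), ".tsv"), "logrank.json")
  manifest_write(out_dir, unclass(config), files)
  invisible(list(signature = sig, deconvolution = dec, strata = strata,
                 km = km, logrank = lr))
}
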