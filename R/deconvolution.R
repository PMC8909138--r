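#' Build a population signature matrix from single-cell profiles
#'
#' For each population, genes over-expressed against all other populations
#' are selected by a one-vs-rest moderated t-test on log2(TPM+1) (Bonferroni
#' adjusted p below `q_cut` and positive log fold change), keeping at most
#' `max_genes_per_pop` genes ranked by t. The signature profiles are the
#' per-population mean TPM over the union of selected genes.
#'
#' @param m An `ExpressionMatrix` on the TPM scale containing all group
#'   members.
#' @param groups List of disjoint `CellGroup`s (e.g. the 22 SCCs and 22
#'   FCCs).
#' @param q_cut Bonferroni-adjusted p cutoff for marker selection.
#' @param max_genes_per_pop Cap on markers per population.
#' @return An object of class `SignatureMatrix` with elements `genes`,
#'   `profiles` (genes x populations mean TPM), `populations`, and
#'   `marker_genes` (per-population selections).
#' @export
build_signature <- function(m, groups, q_cut = 0.01, max_genes_per_pop = 200) {
  stopifnot(inherits(m, "ExpressionMatrix"), length(groups) >= 2)
  if (m$unit_tag != "TPM") stop("build_signature expects a TPM matrix")
  nm <- vapply(groups, `[[`, character(1), "name")
  members <- lapply(groups, `[[`, "cell_ids")
  if (length(unlist(members)) != length(unique(unlist(members))))
    stop("groups must be disjoint")
  lm <- log2_tpm1(m)
  marker_genes <- stats::setNames(vector("list", length(nm)), nm)
  for (i in seq_along(groups)) {
    tab <- moderated_t(lm, members[[i]], unlist(members[-i]))
    sel <- tab[!tab$zero_variance & tab$p_adj < q_cut & tab$logFC > 0, ]
    sel <- sel[order(-sel$t, sel$gene), ]
    marker_genes[[i]] <- utils::head(sel$gene, max_genes_per_pop)
  }
  genes <- sort(unique(unlist(marker_genes)))
  if (!length(genes))
    stop("no differential genes found between populations; ",
         "consider relaxing q_cut")
  profiles <- vapply(members, function(cl)
    rowMeans(m$values[genes, cl, drop = FALSE]), numeric(length(genes)))
  dimnames(profiles) <- list(genes, nm)
  structure(list(genes = genes, profiles = profiles, populations = nm,
                 marker_genes = marker_genes),
            class = "SignatureMatrix")
}

#' @export
print.SignatureMatrix <- function(x, ...) {
  cat(sprintf("SignatureMatrix: %d genes x %d populations (%s)\n",
              length(x$genes), length(x$populations),
              paste(x$populations, collapse = ", ")))
  invisible(x)
}

#' Write a signature matrix as TSV (gene x population)
#'
#' @param sig A `SignatureMatrix`.
#' @param path Output path.
#' @export
write_signature <- function(sig, path) {
  df <- data.frame(gene = sig$genes, sig$profiles, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Absolute-mode deconvolution of bulk samples
#'
#' Estimates per-population scores in each bulk sample by non-negative least
#' squares of the sample's signature-gene expression on the population
#' profiles. Scores are the raw non-negative coefficients (absolute mode: no
#' sum-to-one rescaling), so multiplying a sample by c > 0 scales its scores
#' by c. Significance is assessed by permutation: the sample's signature-gene
#' values are randomly permuted `n_perm` times (default 100), each
#' permutation refit, and the permutation p-value is the +1-smoothed fraction
#' of permutations whose fitted-vs-observed correlation reaches the real one.
#'
#' @param sig A `SignatureMatrix`.
#' @param bulk An `ExpressionMatrix` (genes x samples, TPM). At least half of
#'   the signature genes must be present.
#' @param n_perm Number of gene-label permutations.
#' @param seed Integer seed for the permutations.
#' @return A `DeconvResult` data.frame with one row per sample: one score
#'   column per population, `rmse`, and `p_perm`.
#' @export
deconvolve <- function(sig, bulk, n_perm = 100, seed = 1L) {
  stopifnot(inherits(sig, "SignatureMatrix"),
            inherits(bulk, "ExpressionMatrix"))
  common <- intersect(sig$genes, gene_ids(bulk))
  if (length(common) < 0.5 * length(sig$genes))
    stop("only ", length(common), " of ", length(sig$genes),
         " signature genes present in bulk (< 50%)")
  dropped <- setdiff(sig$genes, common)
  if (length(dropped))
    warning("signature genes absent from bulk dropped: ",
            paste(utils::head(dropped, 10), collapse = ", "))
  if (length(common) < length(sig$populations))
    stop("fewer shared genes than populations")
  A <- sig$profiles[common, , drop = FALSE]
  set.seed(seed)
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(x, y)
  }
  rows <- lapply(cell_ids(bulk), function(s) {
    b <- bulk$values[common, s]
    fit <- pracma::lsqnonneg(A, b)
    x <- fit$x
    fitted <- as.vector(A %*% x)
    r_real <- safe_cor(fitted, b)
    r_null <- vapply(seq_len(n_perm), function(i) {
      bp <- sample(b)
      xp <- pracma::lsqnonneg(A, bp)$x
      safe_cor(as.vector(A %*% xp), bp)
    }, numeric(1))
    data.frame(sample = s, t(stats::setNames(x, sig$populations)),
               rmse = sqrt(mean((b - fitted)^2)),
               p_perm = (1 + sum(r_null >= r_real)) / (n_perm + 1),
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("DeconvResult", "data.frame")
  out
}

#' Stratify samples into high/low by a score cutoff
#'
#' Samples with score strictly above the cutoff (mean by default, matching
#' the mean-cutoff survival stratification; median available) are labelled
#' "high", others — including exact ties — "low".
#'
#' @param scores Named numeric vector of per-sample scores (>= 2 samples).
#' @param rule "mean" or "median".
#' @return Named character vector of labels "high"/"low".
#' @export
stratify_by_score <- function(scores, rule = c("mean", "median")) {
  rule <- match.arg(rule)
  if (length(scores) < 2) stop("need at least 2 samples")
  if (max(scores) == min(scores))
    stop("constant scores: stratification is degenerate")
  cutoff <- if (rule == "mean") mean(scores) else stats::median(scores)
  stats::setNames(ifelse(scores > cutoff, "high", "low"), names(scores))
}
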