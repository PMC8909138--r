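#' Empirical-Bayes moderated t-test between two cell cohorts
#'
#' Per gene, on log2(TPM+1) data: the log fold change is the difference of
#' cohort means; the pooled residual variance s2_g (d_g = nA + nB - 2 df) is
#' shrunk toward a prior (d0, s0^2) estimated by closed-form method of
#' moments on the log sample variances (trigamma inversion by Newton's
#' method, tolerance 1e-8, at most 100 iterations; d0 capped at 1e6 to
#' represent effectively infinite shrinkage). The moderated t uses the
#' posterior variance (d0*s0^2 + d_g*s2_g)/(d0 + d_g) and d0 + d_g degrees of
#' freedom; p-values are two-sided and Bonferroni-adjusted over the tested
#' genes. Genes with zero variance in both cohorts have an undefined t and
#' are reported with p = 1 and a `zero_variance` flag.
#'
#' @param m An `ExpressionMatrix` on the LOG2_TPM1 scale.
#' @param cells_a,cells_b Disjoint cell-id vectors, each of size >= 2.
#' @return A `DegTable` data.frame with columns `gene`, `logFC`, `t`, `p`,
#'   `p_adj`, `significant`, `zero_variance` and attributes `d0`, `s0_sq`.
#' @export
moderated_t <- function(m, cells_a, cells_b) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit_tag != "LOG2_TPM1")
    stop("moderated_t expects LOG2_TPM1 values; apply log2_tpm1() first")
  cells_a <- as.character(cells_a); cells_b <- as.character(cells_b)
  if (length(intersect(cells_a, cells_b)))
    stop("cohorts must be disjoint")
  if (length(cells_a) < 2 || length(cells_b) < 2)
    stop("each cohort needs at least 2 cells")
  missing <- setdiff(c(cells_a, cells_b), cell_ids(m))
  if (length(missing))
    stop("cells not in matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  A <- m$values[, cells_a, drop = FALSE]
  B <- m$values[, cells_b, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  dg <- nA + nB - 2
  if (dg <= 0) stop("zero residual degrees of freedom")
  mA <- rowMeans(A); mB <- rowMeans(B)
  ssA <- rowSums((A - mA)^2); ssB <- rowSums((B - mB)^2)
  s2 <- (ssA + ssB) / dg
  logfc <- mA - mB
  pos <- s2 > 0
  if (!any(pos)) stop("every gene has zero variance in both cohorts")
  prior <- fit_var_prior(s2[pos], dg)
  d0 <- prior$d0; s0_sq <- prior$s0_sq
  s2_post <- (d0 * s0_sq + dg * s2) / (d0 + dg)
  tstat <- logfc / sqrt(s2_post * (1 / nA + 1 / nB))
  df_total <- min(d0 + dg, 1e6)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  zero_var <- !pos
  tstat[zero_var] <- NA_real_
  p[zero_var] <- 1
  p_adj <- pmin(1, p * length(p))
  tab <- data.frame(gene = gene_ids(m), logFC = logfc, t = tstat, p = p,
                    p_adj = p_adj, significant = FALSE,
                    zero_variance = zero_var, row.names = NULL)
  attr(tab, "d0") <- d0
  attr(tab, "s0_sq") <- s0_sq
  attr(tab, "n_a") <- nA
  attr(tab, "n_b") <- nB
  class(tab) <- c("DegTable", "data.frame")
  deg_filter(tab)
}

# Method-of-moments fit of the scaled inverse chi-square prior on gene-wise
# variances, working on log(s2): E[log s2_g] and Var[log s2_g] are known
# functions of (d_g, d0, s0^2) through digamma/trigamma, so matching the
# empirical moments gives d0 by trigamma inversion and s0^2 in closed form.
fit_var_prior <- function(s2, dg, d0_cap = 1e6) {
  z <- log(s2)
  e <- z - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / max(1, n - 1) - trigamma(dg / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    d0 <- min(d0, d0_cap)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- d0_cap
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton inversion of the trigamma function (monotone decreasing on (0, Inf)).
trigamma_inverse <- function(x, tol = 1e-8, max_iter = 100L) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(max_iter)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < tol) break
  }
  y
}

#' Apply significance cutoffs to a DEG table
#'
#' A gene is significant when its Bonferroni-adjusted p-value is below
#' `alpha` (default 0.005) and its |log2 fold change| exceeds `lfc_cut`
#' (default 2). Only the `significant` flag changes.
#'
#' @param tab A `DegTable`.
#' @param alpha Adjusted-p cutoff.
#' @param lfc_cut Absolute log2 fold-change cutoff.
#' @return The table with its `significant` column recomputed.
#' @export
deg_filter <- function(tab, alpha = 0.005, lfc_cut = 2) {
  stopifnot(is.data.frame(tab))
  tab$significant <- !is.na(tab$p_adj) & tab$p_adj < alpha &
    abs(tab$logFC) > lfc_cut
  tab
}

#' Write a DEG table as TSV
#'
#' @param tab A `DegTable`.
#' @param path Output path.
#' @export
write_deg_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Most variable genes
#'
#' Genes ranked by variance across cells, descending; ties broken by gene
#' identifier. The default 1000 genes feed PCA and hierarchical clustering.
#'
#' @param m An `ExpressionMatrix`.
#' @param n Number of genes to return.
#' @return Character vector of gene ids, variance-sorted.
#' @export
top_variable_genes <- function(m, n = 1000) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (n > nrow(m$values)) stop("n exceeds gene count")
  v <- apply(m$values, 1, stats::var)
  gene_ids(m)[order(-v, gene_ids(m))][seq_len(n)]
}

#' Principal-component embedding of cells
#'
#' Centers each gene and projects cells onto the top-k right singular
#' directions (default 3, for the three-dimensional PCA view). Genes are not
#' scaled by default so that variance-ranked genes keep their weight; a
#' `scale` flag is available. Sign convention: the largest-magnitude gene
#' loading of each component is made positive, so embeddings are reproducible
#' across platforms.
#'
#' @param m An `ExpressionMatrix`.
#' @param genes Genes to use (subset of the matrix).
#' @param k Number of components.
#' @param scale Scale genes to unit variance before projection.
#' @return Cells x k coordinate matrix with attributes `loadings` (genes x k)
#'   and `var_explained`.
#' @export
pca_embed <- function(m, genes = gene_ids(m), k = 3, scale = FALSE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  missing <- setdiff(genes, gene_ids(m))
  if (length(missing)) stop("genes not in matrix: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  X <- t(m$values[genes, , drop = FALSE])   # cells x genes
  if (k > min(dim(X))) stop("k exceeds matrix rank bound")
  Xc <- scale(X, center = TRUE, scale = scale)
  if (scale) Xc[, attr(Xc, "scaled:scale") == 0] <- 0
  sv <- svd(Xc, nu = k, nv = k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(sv$v[, j]))
    if (sv$v[i_max, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  coords <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(coords) <- list(cell_ids(m), paste0("PC", seq_len(k)))
  loadings <- sv$v
  dimnames(loadings) <- list(genes, paste0("PC", seq_len(k)))
  attr(coords, "loadings") <- loadings
  attr(coords, "var_explained") <- sv$d[seq_len(k)]^2 / sum(svd(Xc)$d^2)
  coords
}

#' Row z-score standardisation
#'
#' Each gene row becomes (x - mean) / sd; constant rows become all zeros with
#' a warning. Used for marker heatmaps across bulk samples.
#'
#' @param m An `ExpressionMatrix`.
#' @return An `ExpressionMatrix` with `unit_tag = "ZSCORE"`.
#' @export
zscore_rows <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  mu <- rowMeans(m$values)
  sd_ <- apply(m$values, 1, stats::sd)
  const <- sd_ == 0
  if (any(const)) {
    warning(sum(const), " constant rows set to zero")
    sd_[const] <- 1
  }
  vals <- (m$values - mu) / sd_
  vals[const, ] <- 0
  out <- m
  out$values <- vals
  out$unit_tag <- "ZSCORE"
  out
}

#' Agglomerative hierarchical clustering
#'
#' Thin wrapper over average/complete-linkage agglomeration with euclidean or
#' correlation (1 - Pearson) distance; items are the rows of a numeric matrix
#' or the cells of an `ExpressionMatrix`.
#'
#' @param x Numeric matrix (items x features) or `ExpressionMatrix` (cells
#'   clustered over genes).
#' @param linkage "average" or "complete".
#' @param metric "euclidean" or "correlation".
#' @return An `hclust` tree.
#' @export
hcluster <- function(x, linkage = c("average", "complete"),
                     metric = c("euclidean", "correlation")) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  if (inherits(x, "ExpressionMatrix")) x <- t(x$values)
  if (nrow(x) < 2) stop("need at least 2 items to cluster")
  d <- if (metric == "euclidean") stats::dist(x)
       else stats::as.dist(1 - stats::cor(t(x)))
  if (any(!is.finite(d))) stop("non-finite distances")
  stats::hclust(d, method = linkage)
}

#' Serialise an hclust tree as Newick text
#'
#' @param hc An `hclust` object.
#' @param digits Height precision.
#' @return A single Newick string.
#' @export
tree_newick <- function(hc, digits = 6) {
  labs <- hc$labels
  if (is.null(labs)) labs <- as.character(seq_along(hc$order))
  rec <- function(i, parent_h) {
    if (i < 0) return(sprintf("%s:%.*f", labs[-i], digits, parent_h))
    h <- hc$height[i]
    sprintf("(%s,%s):%.*f",
            rec(hc$merge[i, 1], h), rec(hc$merge[i, 2], h),
            digits, parent_h - h)
  }
  n <- nrow(hc$merge)
  h <- hc$height[n]
  paste0("(", rec(hc$merge[n, 1], h), ",", rec(hc$merge[n, 2], h), ");")
}

#' Pairwise Wilcoxon rank-sum comparisons against a reference group
#'
#' Two-sided rank-sum test of the reference group's scores against each other
#' group, using the normal approximation with tie and continuity correction
#' (exact enumeration available for small groups). Cells shared between the
#' reference and a comparator are removed from the comparator. P-values are
#' Bonferroni-adjusted over the number of comparisons.
#'
#' @param scores A `CellScores` covering all group members.
#' @param groups List of `CellGroup`s.
#' @param reference Name of the reference group.
#' @param exact Use the exact distribution (sensible only for n <= 10).
#' @return data.frame with columns `group`, `n_ref`, `n_cmp`, `W`, `p`,
#'   `p_adj`.
#' @export
wilcoxon_pairwise <- function(scores, groups, reference, exact = FALSE) {
  stopifnot(inherits(scores, "CellScores"))
  nm <- vapply(groups, `[[`, character(1), "name")
  if (!reference %in% nm) stop("reference group '", reference, "' not found")
  names(groups) <- nm
  ref_cells <- groups[[reference]]$cell_ids
  check_cells <- function(cl) {
    miss <- setdiff(cl, names(scores$values))
    if (length(miss)) stop("cells without scores: ",
                           paste(utils::head(miss, 5), collapse = ", "))
  }
  check_cells(ref_cells)
  rows <- lapply(setdiff(nm, reference), function(g) {
    cmp <- groups[[g]]$cell_ids
    shared <- intersect(cmp, ref_cells)
    if (length(shared)) {
      warning(length(shared), " cells shared with reference removed from '",
              g, "'")
      cmp <- setdiff(cmp, shared)
    }
    check_cells(cmp)
    if (length(ref_cells) < 3 || length(cmp) < 3)
      stop("group with fewer than 3 cells in comparison '", g, "'")
    wt <- suppressWarnings(stats::wilcox.test(
      scores$values[ref_cells], scores$values[cmp],
      exact = exact, correct = TRUE))
    data.frame(group = g, n_ref = length(ref_cells), n_cmp = length(cmp),
               W = unname(wt$statistic), p = wt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * nrow(out))
  out
}
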