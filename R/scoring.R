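#' Per-cell score container
#'
#' @param score_name Name of the score (e.g. "lipid_metabolism").
#' @param values Named numeric vector, one finite value per cell.
#' @param params List of scoring parameters actually used.
#' @return An object of class `CellScores`.
#' @export
cell_scores <- function(score_name, values, params = list()) {
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop("scores need unique cell names")
  if (!all(is.finite(values))) stop("scores must be finite")
  structure(list(score_name = score_name, values = values, params = params),
            class = "CellScores")
}

#' @export
print.CellScores <- function(x, ...) {
  cat(sprintf("CellScores '%s': %d cells, range [%.4g, %.4g]\n",
              x$score_name, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Export per-cell scores as a two-column TSV
#'
#' @param scores A `CellScores` object.
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  hdr <- sprintf("# score=%s %s", scores$score_name,
                 paste(names(scores$params), unlist(scores$params),
                       sep = "=", collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(
    data.frame(cell_id = names(scores$values), score = scores$values),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Single-sample gene-set enrichment score
#'
#' Rank-based running-sum enrichment evaluated independently in each cell
#' (used for the lipid-metabolism slow-cycling signature). Per cell, genes
#' are ranked by expression; walking the ranking from the most to the least
#' expressed gene, in-set genes increment the running sum by their rank
#' weight `rank^alpha` (normalised by the total in-set weight) and out-of-set
#' genes decrement it by `1/(G - |set|)`. The score is the sum of the running
#' difference over all positions, so cells whose set genes sit near the top
#' of the ranking score high. Because only ranks enter, the score is
#' invariant under any strictly monotone transform of a cell's expression.
#'
#' @param m An `ExpressionMatrix` (TPM or LOG2_TPM1).
#' @param gs A `GeneSet`; at least two of its genes must be present.
#' @param alpha Rank-weighting exponent (default 0.25).
#' @param normalize Divide all cells' scores by (max - min) across cells.
#' @return A `CellScores` object.
#' @export
ssgsea_score <- function(m, gs, alpha = 0.25, normalize = TRUE) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(gs, "GeneSet"))
  if (!m$unit_tag %in% c("TPM", "LOG2_TPM1"))
    stop("ssgsea_score expects TPM or LOG2_TPM1 values")
  genes <- gene_ids(m)
  present <- intersect(gs$genes, genes)
  if (length(present) < 2) {
    missing <- setdiff(gs$genes, genes)
    stop("fewer than 2 genes of set '", gs$name, "' present; missing: ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  G <- length(genes)
  if (length(present) == G)
    stop("gene set covers the whole matrix; complement is empty")
  in_set <- genes %in% present
  miss_dec <- 1 / (G - length(present))
  score_one <- function(x) {
    r <- rank(x, ties.method = "average")
    ord <- order(-x, seq_along(x))       # descending, stable by gene index
    hit <- in_set[ord]
    w <- numeric(G)
    w[hit] <- r[ord][hit]^alpha
    cdf_in <- cumsum(w) / sum(w)
    cdf_out <- cumsum(!hit) * miss_dec
    sum(cdf_in - cdf_out)
  }
  s <- apply(m$values, 2, score_one)
  if (normalize) {
    rng <- max(s) - min(s)
    if (rng > 0) s <- s / rng else warning("constant scores; skipped min-max normalisation")
  }
  cell_scores(gs$name, s,
              params = list(method = "ssgsea", alpha = alpha,
                            normalize = normalize))
}

#' Control-matched module score (Tirosh-style)
#'
#' Scores each cell for a gene program against expression-matched control
#' genes: all genes are binned into `n_bins` equal-frequency bins of average
#' expression; each program gene contributes `n_ctrl` control genes drawn
#' from its own bin; the score is the mean program-gene expression minus the
#' mean over the pooled controls. Used for the G1S and G2M cell-cycle
#' programs.
#'
#' @param m An `ExpressionMatrix` on the LOG2_TPM1 scale.
#' @param gs A `GeneSet`.
#' @param n_bins Number of average-expression bins (default 25).
#' @param n_ctrl Control genes drawn per program gene (default 100; drawn
#'   with replacement when the bin is smaller).
#' @param seed Integer seed controlling the control draw.
#' @return A `CellScores` object.
#' @export
tirosh_module_score <- function(m, gs, n_bins = 25, n_ctrl = 100, seed = 1L) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(gs, "GeneSet"))
  if (m$unit_tag != "LOG2_TPM1")
    stop("tirosh_module_score expects LOG2_TPM1 values")
  genes <- gene_ids(m)
  present <- intersect(gs$genes, genes)
  absent <- setdiff(gs$genes, genes)
  if (!length(present)) stop("no genes of set '", gs$name, "' present")
  if (length(absent))
    warning(length(absent), " genes of set '", gs$name, "' absent; dropped")
  avg <- rowMeans(m$values)
  n_bins <- min(n_bins, length(avg))
  bin <- cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bin) <- genes
  set.seed(seed)
  ctrl_idx <- unlist(lapply(present, function(g) {
    pool <- which(bin == bin[[g]])
    if (length(pool) >= n_ctrl) sample(pool, n_ctrl)
    else sample(pool, n_ctrl, replace = TRUE)
  }))
  prog_mean <- colMeans(m$values[present, , drop = FALSE])
  ctrl_mean <- colMeans(m$values[ctrl_idx, , drop = FALSE])
  cell_scores(gs$name, prog_mean - ctrl_mean,
              params = list(method = "module_score", n_bins = n_bins,
                            n_ctrl = n_ctrl, seed = seed))
}

#' Combined cell-cycle score
#'
#' The cell-cycle score (CCS) of a cell is the sum of its G1S and G2M module
#' scores; the top of the CCS ranking defines the fast-cycling population.
#'
#' @param g1s,g2m `CellScores` over the same cell set.
#' @return A `CellScores` object named "CCS".
#' @export
cell_cycle_score <- function(g1s, g2m) {
  stopifnot(inherits(g1s, "CellScores"), inherits(g2m, "CellScores"))
  if (!setequal(names(g1s$values), names(g2m$values)))
    stop("G1S and G2M scores cover different cell sets")
  v <- g1s$values + g2m$values[names(g1s$values)]
  cell_scores("CCS", v, params = list(method = "sum_g1s_g2m"))
}
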