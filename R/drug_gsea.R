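#' Gene-set enrichment over a signed gene ranking
#'
#' Weighted Kolmogorov-Smirnov enrichment of each gene set against a signed
#' per-gene statistic (typically the moderated t of a two-population DEG
#' contrast, so positive enrichment means the set tracks population A).
#' Genes are ordered by decreasing statistic; in-set genes advance the
#' running sum by their normalised |statistic|^`weight_p` weight, out-of-set
#' genes retreat it by 1/(G - |set|); the enrichment score (ES) is the
#' signed maximum deviation (an exact magnitude tie between the positive and
#' negative extremes reports the positive one). The null distribution comes from gene-label
#' permutation (random same-size sets); NES divides ES by the mean |null ES|
#' of the same sign and the FDR uses the positive/negative NES pooling
#' procedure (Benjamini-Hochberg over permutation p-values available via
#' `fdr_method = "BH"`).
#'
#' @param ranking Named numeric vector: signed statistic per gene.
#' @param collection A `GeneSetCollection`.
#' @param weight_p Weighting exponent on |statistic| (default 1; 0 gives the
#'   classic unweighted KS statistic).
#' @param n_perm Number of gene-label permutations (default 1000).
#' @param seed Integer seed.
#' @param min_size Sets with fewer than this many ranked genes are skipped
#'   with a warning.
#' @param fdr_method "nes_pool" (default) or "BH".
#' @return A `GseaResult` data.frame: `set`, `size`, `ES`, `NES`, `p_perm`,
#'   `fdr`, `direction`.
#' @export
gsea <- function(ranking, collection, weight_p = 1, n_perm = 1000, seed = 1L,
                 min_size = 3, fdr_method = c("nes_pool", "BH")) {
  fdr_method <- match.arg(fdr_method)
  if (!length(collection)) stop("empty gene set collection")
  if (all(ranking == 0)) stop("all ranking statistics are zero")
  if (is.null(names(ranking))) stop("ranking must be named by gene")
  stat <- sort(ranking, decreasing = TRUE)
  ord_names <- names(stat)
  G <- length(stat)
  sizes <- vapply(collection, function(s)
    length(intersect(s$genes, ord_names)), integer(1))
  keep <- sizes >= min_size & sizes < G
  if (any(!keep))
    warning("sets skipped (fewer than ", min_size,
            " ranked genes or covering all genes): ",
            paste(names(collection)[!keep], collapse = ", "))
  collection <- collection[keep]
  sizes <- sizes[keep]
  if (!length(collection)) stop("no testable gene sets after size filter")

  es_for <- function(hit) {
    w <- abs(stat)^weight_p
    w[!hit] <- 0
    sw <- sum(w)
    if (sw == 0) w[hit] <- 1 / sum(hit) else w <- w / sw
    running <- cumsum(w) - cumsum(!hit) / (G - sum(hit))
    mx <- max(running); mn <- min(running)
    if (mx >= -mn - 1e-12) mx else mn  # magnitude ties report the positive
  }

  set.seed(seed)
  res <- lapply(seq_along(collection), function(i) {
    hit <- ord_names %in% collection[[i]]$genes
    es <- es_for(hit)
    null_es <- vapply(seq_len(n_perm), function(b) {
      hb <- logical(G)
      hb[sample.int(G, sizes[i])] <- TRUE
      es_for(hb)
    }, numeric(1))
    same_sign <- null_es[sign(null_es) == sign(es)]
    mean_abs <- mean(abs(same_sign))
    nes <- if (length(same_sign) && mean_abs > 0) es / mean_abs else NA_real_
    p <- if (length(same_sign))
      (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))
    else 1 / (1 + n_perm)
    null_nes <- c(null_es[null_es > 0] /
                    if (any(null_es > 0)) mean(null_es[null_es > 0]) else 1,
                  null_es[null_es < 0] /
                    abs(if (any(null_es < 0)) mean(null_es[null_es < 0]) else 1))
    list(set = collection[[i]]$name, size = sizes[i], ES = es, NES = nes,
         p_perm = p, null_nes = null_nes)
  })
  nes_obs <- vapply(res, `[[`, numeric(1), "NES")
  null_pool <- unlist(lapply(res, `[[`, "null_nes"))
  fdr <- vapply(seq_along(res), function(i) {
    nes <- nes_obs[i]
    if (is.na(nes)) return(1)
    if (nes >= 0) {
      num_null <- mean(null_pool[null_pool >= 0] >= nes)
      den_obs <- mean(nes_obs[!is.na(nes_obs) & nes_obs >= 0] >= nes)
    } else {
      num_null <- mean(null_pool[null_pool <= 0] <= nes)
      den_obs <- mean(nes_obs[!is.na(nes_obs) & nes_obs <= 0] <= nes)
    }
    if (is.na(num_null) || den_obs == 0) return(1)
    min(1, num_null / den_obs)
  }, numeric(1))
  if (fdr_method == "BH")
    fdr <- stats::p.adjust(vapply(res, `[[`, numeric(1), "p_perm"), "BH")
  out <- data.frame(set = vapply(res, `[[`, character(1), "set"),
                    size = vapply(res, `[[`, numeric(1), "size"),
                    ES = vapply(res, `[[`, numeric(1), "ES"),
                    NES = nes_obs,
                    p_perm = vapply(res, `[[`, numeric(1), "p_perm"),
                    fdr = fdr,
                    row.names = NULL)
  out$direction <- ifelse(out$ES >= 0, "A-enriched", "B-enriched")
  class(out) <- c("GseaResult", "data.frame")
  out
}

#' Split significant enrichments by direction
#'
#' Partitions the sets passing the FDR cutoff by NES sign: positive sets are
#' enriched toward the first cohort of the ranking contrast (e.g. drugs
#' predicted to target SCCs), negative toward the second.
#'
#' @param results A `GseaResult` data.frame.
#' @param fdr_cut FDR cutoff (default 0.05).
#' @return List with character vectors `toward_a` and `toward_b`.
#' @export
classify_targets <- function(results, fdr_cut = 0.05) {
  sig <- results[!is.na(results$fdr) & results$fdr < fdr_cut, ]
  list(toward_a = sig$set[sig$NES > 0],
       toward_b = sig$set[sig$NES < 0])
}
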