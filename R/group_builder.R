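#' Cell group container
#'
#' A named set of cells together with the score that ranked them and a record
#' of how they were selected.
#'
#' @param name Group name (e.g. "SCC", "CD133").
#' @param cell_ids Character vector of member cells (unique).
#' @param ranking_score Named numeric vector of the selecting score, one per
#'   member.
#' @param selector List with elements `kind` (one of "signature", "marker",
#'   "cycle"), `source` (score or gene name) and `fraction`.
#' @return An object of class `CellGroup`.
#' @export
cell_group <- function(name, cell_ids, ranking_score,
                       selector = list(kind = "signature", source = name,
                                       fraction = NA_real_)) {
  if (anyDuplicated(cell_ids)) stop("group '", name, "' has duplicate members")
  if (!setequal(names(ranking_score), cell_ids))
    stop("ranking_score must be named by the group members")
  stopifnot(selector$kind %in% c("signature", "marker", "cycle"))
  structure(list(name = name, cell_ids = cell_ids,
                 ranking_score = ranking_score[cell_ids],
                 selector = selector),
            class = "CellGroup")
}

#' @export
print.CellGroup <- function(x, ...) {
  cat(sprintf("CellGroup '%s' (%s on %s): %d cells\n", x$name,
              x$selector$kind, x$selector$source, length(x$cell_ids)))
  invisible(x)
}

#' Select the top-scoring fraction of cells
#'
#' Calls a population as the `ceiling(fraction * N)` highest-scoring cells
#' (top 2% by default, matching the group-size rule that yields 22 cells out
#' of 1091). Score ties at the selection boundary are broken by lexicographic
#' cell identifier so the call is deterministic.
#'
#' @param scores A `CellScores` object.
#' @param fraction Proportion of cells to select, in (0, 1); default 0.02.
#' @param name Group name; defaults to the score name.
#' @param kind Selector kind recorded in the group.
#' @return A `CellGroup`.
#' @export
top_fraction <- function(scores, fraction = 0.02, name = scores$score_name,
                         kind = "signature") {
  stopifnot(inherits(scores, "CellScores"))
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  v <- scores$values
  n <- length(v)
  if (n < 1 / fraction)
    stop("too few cells (", n, ") for fraction ", fraction)
  k <- ceiling(fraction * n)
  if (k == 0) stop("selection size is zero")
  ord <- order(-v, names(v))
  members <- names(v)[ord[seq_len(k)]]
  cell_group(name, members, v[members],
             selector = list(kind = kind, source = scores$score_name,
                             fraction = fraction))
}

#' Call a marker-high population from a single gene
#'
#' Applies [top_fraction()] to one gene's expression vector. Requires at
#' least `ceiling(fraction * N)` cells with strictly positive expression:
#' "highest expression" is meaningless among zeros, so a gene too sparsely
#' expressed is an error rather than a group padded with non-expressers.
#'
#' @param m An `ExpressionMatrix`.
#' @param gene Gene identifier (case-sensitive).
#' @param fraction Proportion of cells to select; default 0.02.
#' @return A `CellGroup` with selector kind "marker".
#' @export
marker_group <- function(m, gene, fraction = 0.02) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!gene %in% gene_ids(m)) {
    near <- agrep(gene, gene_ids(m), max.distance = 0.2, value = TRUE)
    stop("gene '", gene, "' not in matrix",
         if (length(near)) paste0("; near matches: ",
                                  paste(utils::head(near, 5), collapse = ", ")))
  }
  x <- m$values[gene, ]
  k <- ceiling(fraction * length(x))
  if (sum(x > 0) < k)
    stop("gene '", gene, "' has only ", sum(x > 0),
         " positively expressing cells; cannot rank a top-", k, " group")
  sc <- cell_scores(gene, x, params = list(method = "marker"))
  g <- top_fraction(sc, fraction = fraction, name = gene, kind = "marker")
  g
}

#' Max/min-ratio homogeneity check across groups
#'
#' The MMR of a group is the ratio of the largest to the smallest ranking
#' score among its members. A group is flagged when its MMR falls outside the
#' Tukey box-plot fences `[Q1 - whisker*IQR, Q3 + whisker*IQR]` of the MMR
#' distribution over all groups (type-7 quartiles). With a single group,
#' outliers are undefined and nothing is flagged.
#'
#' @param groups List of `CellGroup`s with strictly positive ranking scores.
#' @param whisker Fence multiplier (default 1.5).
#' @return A data.frame (class `MmrReport`) with columns `group`, `mmr`,
#'   `flagged`.
#' @export
mmr_check <- function(groups, whisker = 1.5) {
  stopifnot(length(groups) >= 1,
            all(vapply(groups, inherits, logical(1), "CellGroup")))
  for (g in groups)
    if (any(g$ranking_score <= 0))
      stop("group '", g$name, "' has non-positive ranking scores; MMR undefined")
  mmr <- vapply(groups, function(g)
    max(g$ranking_score) / min(g$ranking_score), numeric(1))
  nm <- vapply(groups, `[[`, character(1), "name")
  if (length(groups) == 1) {
    flagged <- FALSE
  } else {
    q <- stats::quantile(mmr, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    flagged <- mmr < q[1] - whisker * iqr | mmr > q[2] + whisker * iqr
  }
  structure(data.frame(group = nm, mmr = mmr, flagged = flagged,
                       row.names = NULL),
            class = c("MmrReport", "data.frame"))
}

#' Iteratively shrink flagged groups until MMR homogeneity
#'
#' Optional refinement of the group-size rule: while any group is flagged by
#' [mmr_check()], its lowest-scoring member is dropped and the check is
#' repeated. Flagged groups are otherwise reported, never silently altered.
#'
#' @inheritParams mmr_check
#' @param max_iter Safety cap on shrink iterations.
#' @return The list of (possibly shrunk) `CellGroup`s.
#' @export
mmr_shrink <- function(groups, whisker = 1.5, max_iter = 100L) {
  for (i in seq_len(max_iter)) {
    rep <- mmr_check(groups, whisker)
    if (!any(rep$flagged)) return(groups)
    j <- which(rep$flagged)[1]
    g <- groups[[j]]
    if (length(g$cell_ids) <= 2)
      stop("group '", g$name, "' cannot shrink below 2 cells")
    keep <- g$cell_ids[order(-g$ranking_score, g$cell_ids)]
    keep <- keep[-length(keep)]
    groups[[j]] <- cell_group(g$name, keep, g$ranking_score[keep], g$selector)
  }
  warning("mmr_shrink did not converge in ", max_iter, " iterations")
  groups
}

#' Overlap structure of a set of cell groups
#'
#' Exact set arithmetic over group memberships: pairwise intersection sizes,
#' per-group private-cell counts (cells belonging to no other group), the
#' per-cell membership map, and the exclusive-intersection (upset) counts.
#' Pairwise overlap is also reported as a fraction of the smaller group and
#' as the Jaccard index.
#'
#' @param groups List of at least two `CellGroup`s with unique names.
#' @return An object of class `GroupOverlap`.
#' @export
compute_overlap <- function(groups) {
  stopifnot(length(groups) >= 2,
            all(vapply(groups, inherits, logical(1), "CellGroup")))
  nm <- vapply(groups, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate group names: ", paste(nm[duplicated(nm)], collapse = ", "))
  names(groups) <- nm
  members <- lapply(groups, `[[`, "cell_ids")
  all_cells <- sort(unique(unlist(members)))
  membership <- lapply(stats::setNames(all_cells, all_cells), function(cl)
    unname(nm[vapply(members, function(mm) cl %in% mm, logical(1))]))
  n_groups_per_cell <- lengths(membership)
  privates <- vapply(nm, function(g)
    sum(vapply(membership, function(gs) identical(gs, g), logical(1))),
    integer(1))
  pairwise <- matrix(0L, length(nm), length(nm), dimnames = list(nm, nm))
  frac_min <- jaccard <- matrix(0, length(nm), length(nm),
                                dimnames = list(nm, nm))
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    inter <- length(intersect(members[[i]], members[[j]]))
    pairwise[i, j] <- inter
    if (i != j) {
      frac_min[i, j] <- inter / min(lengths(members)[c(i, j)])
      jaccard[i, j] <- inter / length(union(members[[i]], members[[j]]))
    }
  }
  sig <- vapply(membership, function(gs) paste(sort(gs), collapse = "&"),
                character(1))
  upset <- table(sig)
  structure(list(group_names = nm, pairwise = pairwise, privates = privates,
                 membership = membership, upset = upset,
                 overlap_fraction = frac_min, jaccard = jaccard,
                 n_union = length(all_cells)),
            class = "GroupOverlap")
}

#' @export
print.GroupOverlap <- function(x, ...) {
  cat("GroupOverlap over", length(x$group_names), "groups;",
      x$n_union, "cells in union\nprivates:\n")
  print(x$privates)
  invisible(x)
}

#' Multi-marker combination CSC population
#'
#' Cells simultaneously in the top fraction of at least two marker-high
#' groups. Defined over the five marker groups only; passing signature- or
#' cycle-selected groups (SCC/FCC) is an error. Each combo cell is annotated
#' with the specific marker pair(s) it belongs to.
#'
#' @param marker_groups List of `CellGroup`s, all with selector kind
#'   "marker".
#' @return A `CellGroup` named "Combo_CSC" whose ranking score is the number
#'   of marker groups each cell belongs to, with a `pairs` attribute mapping
#'   each cell to its marker pairs.
#' @export
combo_csc <- function(marker_groups) {
  stopifnot(length(marker_groups) >= 2,
            all(vapply(marker_groups, inherits, logical(1), "CellGroup")))
  kinds <- vapply(marker_groups, function(g) g$selector$kind, character(1))
  if (any(kinds != "marker"))
    stop("combo_csc is defined over marker groups only; got selector kind: ",
         paste(unique(kinds[kinds != "marker"]), collapse = ", "))
  nm <- vapply(marker_groups, `[[`, character(1), "name")
  members <- stats::setNames(lapply(marker_groups, `[[`, "cell_ids"), nm)
  all_cells <- sort(unique(unlist(members)))
  in_groups <- lapply(stats::setNames(all_cells, all_cells), function(cl)
    unname(nm[vapply(members, function(mm) cl %in% mm, logical(1))]))
  combo <- names(in_groups)[lengths(in_groups) >= 2]
  pairs <- lapply(in_groups[combo], function(gs)
    apply(utils::combn(sort(gs), 2), 2, paste, collapse = "/"))
  score <- stats::setNames(as.numeric(lengths(in_groups[combo])), combo)
  g <- cell_group("Combo_CSC", combo, score,
                  selector = list(kind = "marker", source = "combined",
                                  fraction = NA_real_))
  attr(g, "pairs") <- pairs
  g
}

#' Private cells of a group
#'
#' Members of the named group belonging to no other group; these cohorts are
#' the inputs to differential expression.
#'
#' @param groups List of `CellGroup`s.
#' @param g Name of the group whose private cells are wanted.
#' @return Character vector of cell identifiers.
#' @export
private_cells <- function(groups, g) {
  nm <- vapply(groups, `[[`, character(1), "name")
  if (!g %in% nm) stop("unknown group: ", g)
  names(groups) <- nm
  others <- unlist(lapply(groups[nm != g], `[[`, "cell_ids"))
  setdiff(groups[[g]]$cell_ids, others)
}

#' Export groups as a two-column TSV (cell_id, group)
#'
#' @param groups List of `CellGroup`s.
#' @param path Output path.
#' @export
write_groups <- function(groups, path) {
  df <- do.call(rbind, lapply(groups, function(g)
    data.frame(cell_id = g$cell_ids, group = g$name)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export overlap counts as JSON
#'
#' @param ov A `GroupOverlap`.
#' @param path Output path.
#' @export
write_overlap_json <- function(ov, path) {
  jsonlite::write_json(
    list(groups = ov$group_names,
         privates = as.list(ov$privates),
         pairwise = as.data.frame(ov$pairwise),
         upset = as.list(ov$upset),
         n_union = ov$n_union),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
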