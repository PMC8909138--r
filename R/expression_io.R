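#' Construct a validated expression matrix
#'
#' The working container for every stage of the pipeline: a genes x cells (or
#' genes x samples) abundance matrix with unique row/column identifiers and a
#' unit tag recording the scale the values are on.
#'
#' @param values Numeric matrix with gene identifiers as rownames and cell (or
#'   sample) identifiers as colnames.
#' @param unit_tag One of `"TPM"` (non-negative transcripts per million),
#'   `"LOG2_TPM1"` (log2(TPM + 1)) or `"ZSCORE"` (row-standardised).
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `unit_tag`.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("c1", "c2")))
#' em <- expression_matrix(m)
#' gene_ids(em)
#' @export
expression_matrix <- function(values, unit_tag = c("TPM", "LOG2_TPM1", "ZSCORE")) {
  unit_tag <- match.arg(unit_tag)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and cell colnames")
  dup_g <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_g))
    stop("duplicate gene identifiers: ", paste(unique(dup_g), collapse = ", "))
  dup_c <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_c))
    stop("duplicate cell identifiers: ", paste(unique(dup_c), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  if (unit_tag == "TPM" && any(values < 0))
    stop("negative values are not valid TPM abundances")
  structure(list(values = values, unit_tag = unit_tag),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d genes x %d cells\n",
              x$unit_tag, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @rdname expression_matrix
#' @param m An `ExpressionMatrix`.
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname expression_matrix
#' @export
cell_ids <- function(m) colnames(m$values)

#' Read an expression matrix from disk
#'
#' Supports a dense TSV (genes x cells with a header row of cell identifiers
#' and gene identifiers in the first column) and Matrix Market coordinate
#' format (`.mtx`) accompanied by plain-text gene and cell name files, one
#' identifier per line.
#'
#' @param path Path to the TSV or MTX file.
#' @param format `"tsv"` or `"mtx"`.
#' @param transpose If `TRUE` the source stores cells x genes and is
#'   transposed on read.
#' @param sep Field separator for the dense reader (default tab; `","` for
#'   CSV sources).
#' @param genes_path,cells_path Sibling identifier files for MTX input;
#'   default `<stem>_genes.txt` / `<stem>_cells.txt`.
#' @return A validated [expression_matrix()] with `unit_tag = "TPM"`.
#' @export
read_expression <- function(path, format = c("tsv", "mtx"), transpose = FALSE,
                            sep = "\t",
                            genes_path = NULL, cells_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, quote = "",
                            comment.char = "")
    vals <- as.matrix(df)
  } else {
    stem <- sub("\\.mtx$", "", path)
    if (is.null(genes_path)) genes_path <- paste0(stem, "_genes.txt")
    if (is.null(cells_path)) cells_path <- paste0(stem, "_cells.txt")
    for (p in c(genes_path, cells_path))
      if (!file.exists(p)) stop("MTX sibling name file not found: ", p)
    sp <- tryCatch(Matrix::readMM(path), error = function(e)
      stop("parse error in ", path, ": ", conditionMessage(e)))
    vals <- as.matrix(sp)
    g <- readLines(genes_path)
    cl <- readLines(cells_path)
    if (length(g) != nrow(vals) || length(cl) != ncol(vals))
      stop("identifier files do not match matrix dimensions (",
           length(g), " genes / ", length(cl), " cells vs ",
           nrow(vals), " x ", ncol(vals), ")")
    dimnames(vals) <- list(g, cl)
  }
  if (transpose) vals <- t(vals)
  expression_matrix(vals, unit_tag = "TPM")
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression()]; round-trips values at full precision.
#'
#' @inheritParams read_expression
#' @param m An `ExpressionMatrix`.
#' @export
write_expression <- function(m, path, format = c("tsv", "mtx"), sep = "\t") {
  format <- match.arg(format)
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (format == "tsv") {
    df <- data.frame(gene_id = gene_ids(m), m$values, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  } else {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE), path)
    writeLines(gene_ids(m), paste0(stem, "_genes.txt"))
    writeLines(cell_ids(m), paste0(stem, "_cells.txt"))
  }
  invisible(path)
}

#' Gene set and gene set collection constructors
#'
#' @param name Set name.
#' @param genes Character vector of gene identifiers (non-empty, no
#'   duplicates).
#' @return `gene_set()` returns a `GeneSet`; `gene_set_collection()` a
#'   `GeneSetCollection` (a named list of `GeneSet`s with unique names).
#' @export
gene_set <- function(name, genes) {
  genes <- as.character(genes)
  if (!length(genes)) stop("gene set '", name, "' is empty")
  if (anyDuplicated(genes))
    stop("gene set '", name, "' contains duplicate genes")
  structure(list(name = name, genes = genes), class = "GeneSet")
}

#' @rdname gene_set
#' @param sets List of `GeneSet` objects.
#' @export
gene_set_collection <- function(sets = list()) {
  stopifnot(all(vapply(sets, inherits, logical(1), "GeneSet")))
  nm <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate gene set names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(sets) <- nm
  structure(sets, class = "GeneSetCollection")
}

#' Read gene sets in GMT format
#'
#' One set per line, tab-separated: name, description, then member genes.
#' The description column is discarded; duplicated genes within a line are
#' deduplicated with a warning.
#'
#' @param path Path to the GMT file.
#' @return A `GeneSetCollection`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT parse error at line ", i,
           ": expected at least 3 tab-separated fields")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in set '", f[[1]], "' deduplicated")
      genes <- unique(genes)
    }
    sets[[i]] <- gene_set(f[[1]], genes)
  }
  gene_set_collection(sets)
}

#' Write a gene set collection in GMT format
#'
#' @param collection A `GeneSetCollection`.
#' @param path Output path.
#' @param description Description field written for every set.
#' @export
write_gmt <- function(collection, path, description = "na") {
  lines <- vapply(collection, function(s)
    paste(c(s$name, description, s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Filter genes by mean abundance and breadth of expression
#'
#' Keeps genes whose mean TPM over all cells exceeds `mean_tpm_min` and that
#' are expressed (TPM > 0) in at least `min_cells` cells. The cell set and
#' the order of surviving genes are unchanged.
#'
#' @param m An `ExpressionMatrix` on the TPM scale.
#' @param mean_tpm_min Mean-TPM threshold (strict inequality); default 0.2.
#' @param min_cells Minimum number of expressing cells; default 30.
#' @return A filtered `ExpressionMatrix`.
#' @export
filter_genes <- function(m, mean_tpm_min = 0.2, min_cells = 30) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit_tag != "TPM") stop("filter_genes expects a TPM matrix")
  keep <- rowMeans(m$values) > mean_tpm_min &
    rowSums(m$values > 0) >= min_cells
  if (!any(keep))
    stop("no genes survive filtering; review mean_tpm_min/min_cells thresholds")
  expression_matrix(m$values[keep, , drop = FALSE], unit_tag = "TPM")
}

#' Log-transform a TPM matrix
#'
#' Applies log2(TPM + 1), the working scale for differential expression,
#' module scoring and PCA.
#'
#' @param m An `ExpressionMatrix` on the TPM scale.
#' @return An `ExpressionMatrix` with `unit_tag = "LOG2_TPM1"`.
#' @export
log2_tpm1 <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit_tag != "TPM") stop("log2_tpm1 expects a TPM matrix")
  out <- m
  out$values <- log2(m$values + 1)
  out$unit_tag <- "LOG2_TPM1"
  out
}
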