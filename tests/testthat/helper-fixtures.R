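# Small in-code fixtures shared across test files.

toy_matrix <- function(n_genes = 6, n_cells = 8, seed = 1, unit = "TPM") {
  set.seed(seed)
  vals <- matrix(stats::rlnorm(n_genes * n_cells), n_genes, n_cells,
                 dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                 sprintf("c%02d", seq_len(n_cells))))
  expression_matrix(vals, unit)
}

# ExpressionMatrix on the log scale from raw numbers (bypasses the TPM
# non-negativity rule, which does not apply to log data).
log_matrix <- function(vals) {
  expression_matrix(abs(vals) + 1, "TPM") -> m  # validate ids/shape
  m$values <- vals
  m$unit_tag <- "LOG2_TPM1"
  m
}

named_scores <- function(v, prefix = "c") {
  cell_scores("toy", stats::setNames(v, sprintf("%s%02d", prefix,
                                                seq_along(v))))
}

make_group <- function(name, ids, scores = NULL, kind = "marker") {
  if (is.null(scores)) scores <- rev(seq_along(ids))
  cell_group(name, ids, stats::setNames(as.numeric(scores), ids),
             selector = list(kind = kind, source = name, fraction = 0.02))
}
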