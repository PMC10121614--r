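#' Per-cell quality-control metrics
#'
#' @param matrix a `SingleCellExperiment` whose gene metadata carries an
#'   `is_mito` flag (see [cell_counts()]).
#' @return data.frame with one row per cell: `cell_id`, `n_genes_detected`,
#'   `total_counts`, `pct_mito` (percent of counts from mitochondrial genes;
#'   0 by convention for empty cells).
#' @export
compute_qc_metrics <- function(matrix) {
  m <- counts_assay(matrix)
  is_mito <- gene_meta_df(matrix)$is_mito
  total <- Matrix::colSums(m)
  mito <- if (any(is_mito)) Matrix::colSums(m[is_mito, , drop = FALSE]) else 0
  data.frame(
    cell_id = colnames(m),
    n_genes_detected = Matrix::colSums(m > 0),
    total_counts = total,
    pct_mito = ifelse(total > 0, 100 * mito / total, 0),
    row.names = NULL
  )
}

#' Quality-control thresholds
#'
#' Defaults are the study's gates: 250-8000 detected genes and 1000-100000
#' transcripts (both bounds inclusive), and strictly less than 30 percent
#' mitochondrial transcripts.
#'
#' @param min_genes,max_genes inclusive bounds on detected genes.
#' @param min_counts,max_counts inclusive bounds on total transcripts.
#' @param max_pct_mito exclusive upper bound on percent mitochondrial.
#' @return a `perfuseq_qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes = 250, max_genes = 8000,
                          min_counts = 1000, max_counts = 100000,
                          max_pct_mito = 30) {
  stopifnot(min_genes < max_genes, min_counts < max_counts,
            max_pct_mito > 0, max_pct_mito <= 100)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 min_counts = min_counts, max_counts = max_counts,
                 max_pct_mito = max_pct_mito),
            class = "perfuseq_qc_thresholds")
}

#' Filter cells on QC metrics
#'
#' Retains exactly the cells inside the closed gene/count intervals and below
#' the mitochondrial gate; cell order and the gene set are unchanged.
#'
#' @param matrix a `SingleCellExperiment`.
#' @param metrics output of [compute_qc_metrics()] aligned to `matrix`.
#' @param thresholds a [qc_thresholds()] object.
#' @return the filtered `SingleCellExperiment`.
#' @export
filter_cells <- function(matrix, metrics = compute_qc_metrics(matrix),
                         thresholds = qc_thresholds()) {
  if (!identical(metrics$cell_id, colnames(matrix))) {
    stop("metrics are not aligned to the matrix cells")
  }
  t <- thresholds
  keep <- metrics$n_genes_detected >= t$min_genes &
    metrics$n_genes_detected <= t$max_genes &
    metrics$total_counts >= t$min_counts &
    metrics$total_counts <= t$max_counts &
    metrics$pct_mito < t$max_pct_mito
  message(sprintf("filter_cells: retained %d/%d cells (genes out: %d, counts out: %d, pct_mito out: %d)",
                  sum(keep), length(keep),
                  sum(metrics$n_genes_detected < t$min_genes | metrics$n_genes_detected > t$max_genes),
                  sum(metrics$total_counts < t$min_counts | metrics$total_counts > t$max_counts),
                  sum(metrics$pct_mito >= t$max_pct_mito)))
  matrix[, keep]
}

#' Flag or remove doublets before clustering
#'
#' Preferred route: truth labels (an `is_doublet` metadata column, e.g. from
#' the generator). Fallback heuristic: flag cells above the 99.5th
#' percentile of total counts.
#'
#' @param matrix a `SingleCellExperiment`.
#' @param quantile percentile of total counts above which the heuristic
#'   flags cells when no labels are present.
#' @return the matrix with flagged cells removed.
#' @export
remove_doublets <- function(matrix, quantile = 0.995) {
  meta <- cell_meta_df(matrix)
  if (!is.null(meta$is_doublet) && !all(is.na(meta$is_doublet))) {
    drop <- meta$is_doublet %in% TRUE
  } else {
    tot <- Matrix::colSums(counts_assay(matrix))
    drop <- tot > stats::quantile(tot, quantile)
  }
  message(sprintf("remove_doublets: removed %d/%d cells", sum(drop), length(drop)))
  matrix[, !drop]
}
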