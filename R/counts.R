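#' Build a cell-level count container
#'
#' Wraps a gene x cell integer count matrix and its aligned metadata into a
#' [SingleCellExperiment::SingleCellExperiment], the substrate of every
#' pipeline stage. Genes are rows, cells are columns.
#'
#' @param counts gene x cell matrix of nonnegative integers (dense or
#'   `Matrix` sparse). Row names are gene symbols, column names cell ids.
#' @param cell_meta data.frame with one row per cell: `cell_id`, `patient`,
#'   `timepoint` (one of `"T0"`, `"T1"`, `"T2"`), and optionally `cell_type`,
#'   `subcluster`, `is_doublet`.
#' @param gene_meta data.frame with one row per gene: `symbol` and optionally
#'   `is_mito`. When `is_mito` is absent it is derived from a
#'   case-insensitive `"MT-"` symbol prefix.
#' @return A `SingleCellExperiment` with a `counts` assay.
#' @export
cell_counts <- function(counts, cell_meta, gene_meta = NULL) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  counts <- methods::as(counts, "dMatrix")
  if (any(counts@x < 0)) stop("counts must be nonnegative")
  if (any(counts@x != round(counts@x))) stop("counts must be integral")
  if (is.null(gene_meta)) {
    sym <- rownames(counts)
    if (is.null(sym)) sym <- sprintf("gene%04d", seq_len(nrow(counts)))
    gene_meta <- data.frame(symbol = sym)
  }
  if (is.null(gene_meta$is_mito)) {
    gene_meta$is_mito <- grepl("^mt-", gene_meta$symbol, ignore.case = TRUE)
  }
  stopifnot(nrow(gene_meta) == nrow(counts), nrow(cell_meta) == ncol(counts))
  if (anyDuplicated(gene_meta$symbol)) stop("gene symbols must be unique")
  if (anyDuplicated(cell_meta$cell_id)) {
    dup <- cell_meta$cell_id[duplicated(cell_meta$cell_id)][1L]
    stop("duplicate cell id: ", dup)
  }
  if (!all(cell_meta$timepoint %in% c("T0", "T1", "T2"))) {
    stop("timepoint labels must be T0/T1/T2")
  }
  rownames(counts) <- gene_meta$symbol
  colnames(counts) <- cell_meta$cell_id
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(cell_meta, row.names = cell_meta$cell_id),
    rowData = S4Vectors::DataFrame(gene_meta, row.names = gene_meta$symbol)
  )
}

# internal fast path: inputs already validated
.new_sce <- function(counts, cell_meta, gene_meta) {
  rownames(counts) <- gene_meta$symbol
  colnames(counts) <- cell_meta$cell_id
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(cell_meta, row.names = cell_meta$cell_id),
    rowData = S4Vectors::DataFrame(gene_meta, row.names = gene_meta$symbol)
  )
}

counts_assay <- function(x) SummarizedExperiment::assay(x, "counts")

cell_meta_df <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

gene_meta_df <- function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))
}

#' Median-depth log-normalization
#'
#' Scales each cell's counts to the median total depth, then applies
#' `log1p`. This is the normalization used for annotation scoring, marker
#' dot values and communication mean-expression summaries.
#'
#' @param x a `SingleCellExperiment` with a `counts` assay.
#' @return sparse gene x cell matrix of log-normalized values.
#' @export
lognorm_counts <- function(x) {
  m <- counts_assay(x)
  tot <- Matrix::colSums(m)
  target <- stats::median(tot[tot > 0])
  sf <- ifelse(tot > 0, tot / target, 1)
  m2 <- m %*% Matrix::Diagonal(x = 1 / sf)
  dimnames(m2) <- dimnames(m)
  m2@x <- log1p(m2@x)
  m2
}
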