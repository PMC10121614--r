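#' Subcluster cells within one cell type
#'
#' Restricts the matrix to the annotated cells of `cell_type` and reuses
#' [cluster_cells()] on them; deterministic for a fixed seed.
#'
#' @param matrix an annotated `SingleCellExperiment` (cells carry
#'   `cell_type`).
#' @param cell_type which population to subcluster.
#' @param hvgs optional clustering genes; defaults to all genes.
#' @param n_pcs,k_neighbors,resolution,seed see [cluster_cells()].
#' @param min_cells minimum population size.
#' @return a `perfuseq_clusters` object over the cell type's cells.
#' @export
subcluster <- function(matrix, cell_type, hvgs = NULL, n_pcs = 20,
                       k_neighbors = 15, resolution = 0.5, seed = 0L,
                       min_cells = 50) {
  sel <- cell_meta_df(matrix)$cell_type %in% cell_type
  if (sum(sel) < min_cells) {
    stop("fewer than ", min_cells, " cells of type ", cell_type)
  }
  sub <- matrix[, sel]
  if (is.null(hvgs)) hvgs <- rownames(sub)
  cluster_cells(sub, hvgs = hvgs, n_pcs = n_pcs, k_neighbors = k_neighbors,
                resolution = resolution, seed = seed)
}

#' Area under the ROC curve for a two-group comparison
#'
#' The probability that a random in-group value exceeds a random out-group
#' value, with ties counted half:
#' `(#pairs g > r + 0.5 * #ties) / (n_g * n_r)`. Equals the Mann-Whitney U
#' statistic divided by `n_g * n_r` and is invariant under strictly
#' monotone transforms.
#'
#' @param values_group,values_rest nonempty numeric vectors.
#' @return AUROC in `[0, 1]`; 0.5 for identical constant vectors.
#' @export
compute_auroc <- function(values_group, values_rest) {
  n_g <- length(values_group)
  n_r <- length(values_rest)
  if (n_g == 0 || n_r == 0) stop("both groups must be nonempty")
  r <- rank(c(values_group, values_rest))
  u <- sum(r[seq_len(n_g)]) - n_g * (n_g + 1) / 2
  u / (n_g * n_r)
}

#' Marker thresholds per cell type
#'
#' AUROC and log2 fold-change gates: `(0.7, 1)` for neutrophils, `(0.7, 2)`
#' for monocytes/macrophages, `(0.7, 1)` otherwise.
#'
#' @param cell_type cell-type name.
#' @return list with `auroc_min` and `lfc_min`.
#' @export
marker_thresholds <- function(cell_type) {
  registry <- list(
    neutrophil = list(auroc_min = 0.7, lfc_min = 1),
    mono_mac = list(auroc_min = 0.7, lfc_min = 2)
  )
  registry[[cell_type]] %||% list(auroc_min = 0.7, lfc_min = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call subcluster marker genes on patient-level pseudo-bulk
#'
#' Genes expressed in at least `min_expr_fraction` of the supplied cells are
#' summed per (subcluster, patient), pooling timepoints; samples below the
#' count/cell floors are dropped. Pseudo-bulk profiles are normalized to
#' `log2(CPM + 1)` and each subcluster is compared one-vs-rest: a gene is a
#' marker when its AUROC exceeds `auroc_min` and its mean log2-CPM
#' difference exceeds `lfc_min`.
#'
#' @param matrix a `SingleCellExperiment` restricted to one cell type.
#' @param labels per-cell subcluster labels aligned to `matrix` columns.
#' @param auroc_min,lfc_min marker gates (see [marker_thresholds()]).
#' @param min_expr_fraction,min_counts,min_cells pseudo-bulk retention rules.
#' @return data.frame (`subcluster`, `gene`, `auroc`, `log2fc`, `is_marker`)
#'   with the thresholds in attributes.
#' @export
call_markers <- function(matrix, labels, auroc_min = 0.7, lfc_min = 1,
                         min_expr_fraction = 0.05, min_counts = 1000,
                         min_cells = 10) {
  stopifnot(length(labels) == ncol(matrix))
  if (length(unique(labels)) < 2) stop("need at least two subclusters")
  meta <- cell_meta_df(matrix)
  if (length(unique(meta$patient)) < 2) stop("need at least two patients")
  m <- counts_assay(matrix)
  keep_genes <- Matrix::rowSums(m > 0) >= min_expr_fraction * ncol(m)
  m <- m[keep_genes, , drop = FALSE]

  grp <- interaction(labels, meta$patient, drop = TRUE, sep = "|")
  agg <- as.matrix(m %*% Matrix::sparse.model.matrix(~ 0 + grp))
  colnames(agg) <- sub("^grp", "", colnames(agg))
  n_cells <- as.integer(table(grp)[colnames(agg)])
  keep <- colSums(agg) >= min_counts & n_cells >= min_cells
  if (any(!keep)) {
    message(sprintf("call_markers: discarded %d/%d pseudo-bulk samples",
                    sum(!keep), length(keep)))
  }
  agg <- agg[, keep, drop = FALSE]
  sub_of <- vapply(strsplit(colnames(agg), "|", fixed = TRUE), `[`, "", 1)
  logcpm <- log2(sweep(agg, 2, colSums(agg) / 1e6, `/`) + 1)

  res <- list()
  for (s in sort(unique(as.character(labels)))) {
    idx <- sub_of == s
    if (sum(idx) < 2 || sum(!idx) < 1) {
      warning("subcluster ", s, " has <2 pseudo-bulk samples; excluded")
      next
    }
    auroc <- apply(logcpm, 1, function(v) compute_auroc(v[idx], v[!idx]))
    lfc <- rowMeans(logcpm[, idx, drop = FALSE]) -
      rowMeans(logcpm[, !idx, drop = FALSE])
    res[[s]] <- data.frame(subcluster = s, gene = rownames(logcpm),
                           auroc = auroc, log2fc = lfc,
                           is_marker = auroc > auroc_min & lfc > lfc_min,
                           row.names = NULL)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "thresholds") <- list(auroc_min = auroc_min, lfc_min = lfc_min)
  attr(out, "normalization") <- "log2(CPM + 1) on pseudo-bulk"
  out
}
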