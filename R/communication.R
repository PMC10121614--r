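#' Mean-of-patient expression fraction
#'
#' The fraction of a cell type's cells detecting a gene (count > 0),
#' computed per patient and then averaged with equal patient weights. The
#' unweighted mean neutralizes unequal per-patient cell capture: replicating
#' one patient's cells leaves the result exactly unchanged.
#'
#' @param matrix a `SingleCellExperiment` with `cell_type` and `patient`
#'   metadata.
#' @param gene gene symbol.
#' @param cell_type receiver cell type.
#' @return fraction in `[0, 1]`, or `NA` when no cell of that type exists.
#' @export
expression_fraction <- function(matrix, gene, cell_type) {
  ft <- fraction_table(matrix, gene)
  if (!cell_type %in% colnames(ft)) return(NA_real_)
  ft[gene, cell_type]
}

#' Per-gene, per-cell-type fraction and mean-expression tables
#'
#' Vectorized backend of [expression_fraction()]: for each requested gene
#' and each annotated cell type, the mean over patients of the per-patient
#' detection fraction, and (optionally) the mean over patients of the
#' per-patient mean log-normalized expression.
#'
#' @param matrix a `SingleCellExperiment`.
#' @param genes genes to tabulate (must exist in the matrix).
#' @param what `"fraction"` or `"mean_expr"`.
#' @return gene x cell-type matrix; `NA` where a cell type has no cells.
#' @export
fraction_table <- function(matrix, genes, what = c("fraction", "mean_expr")) {
  what <- match.arg(what)
  stopifnot(all(genes %in% rownames(matrix)))
  meta <- cell_meta_df(matrix)
  types <- sort(unique(stats::na.omit(meta$cell_type)))
  vals <- if (what == "fraction") {
    counts_assay(matrix)[genes, , drop = FALSE] > 0
  } else {
    lognorm_counts(matrix)[genes, , drop = FALSE]
  }
  out <- matrix(NA_real_, length(genes), length(types),
                dimnames = list(genes, types))
  for (tname in types) {
    sel <- which(meta$cell_type %in% tname)
    pats <- meta$patient[sel]
    per_patient <- vapply(unique(pats), function(p) {
      Matrix::rowMeans(vals[, sel[pats == p], drop = FALSE])
    }, numeric(length(genes)))
    per_patient <- matrix(per_patient, nrow = length(genes))
    out[, tname] <- rowMeans(per_patient)
  }
  out
}

#' Significantly differential ligands per sender cell type
#'
#' Intersects each cell type's differential-expression result with the
#' ligand genes of the interaction database and keeps genes with
#' `padj <= ligand_fdr`. A multi-subunit ligand qualifies when any of its
#' subunits passes.
#'
#' @param de_list named list: sender cell type -> result of
#'   [test_differential_expression()].
#' @param db ligand-receptor table (`interaction`, `ligand`, `receptor`,
#'   `pathway`; subunits joined by `+`), e.g. [read_lr_database()] output.
#' @param ligand_fdr significance gate on adjusted p-values.
#' @return data.frame (`sender`, `ligand`, `log2fc`, `padj`, `direction`).
#' @export
differential_ligands <- function(de_list, db, ligand_fdr = 0.05) {
  if (is.null(db) || nrow(db) == 0) stop("empty ligand-receptor database")
  ligand_genes <- unique(unlist(strsplit(db$ligand, "+", fixed = TRUE)))
  out <- list()
  for (sender in names(de_list)) {
    de <- de_list[[sender]]
    hit <- de[de$gene %in% ligand_genes & !is.na(de$padj) &
                de$padj <= ligand_fdr, , drop = FALSE]
    if (!nrow(hit)) next
    out[[sender]] <- data.frame(
      sender = sender, ligand = hit$gene, log2fc = hit$log2fc,
      padj = hit$padj, direction = ifelse(hit$log2fc > 0, "up", "down"),
      row.names = NULL)
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(sender = character(), ligand = character(),
               log2fc = numeric(), padj = numeric(), direction = character())
  }
  rownames(res) <- NULL
  res[order(res$sender, res$ligand), , drop = FALSE]
}

#' Build timepoint-differential communication edges
#'
#' For every differential ligand of a sender, every database interaction
#' containing it, and every candidate receiver cell type (the sender
#' included, so autocrine loops are allowed), an edge is emitted when every
#' receptor subunit is detected in at least `min_fraction` of the
#' receiver's cells (mean of per-patient fractions). The edge carries the
#' minimum subunit fraction and the mean over subunits of the
#' patient-averaged mean log-normalized expression.
#'
#' @param ligands output of [differential_ligands()].
#' @param db the ligand-receptor table.
#' @param matrix the annotated `SingleCellExperiment` (all cell types).
#' @param min_fraction receptor detection gate (default 10 percent).
#' @return data.frame of edges sorted by (sender, ligand, receiver,
#'   receptor).
#' @export
build_edges <- function(ligands, db, matrix, min_fraction = 0.10) {
  empty <- data.frame(sender = character(), ligand = character(),
                      interaction = character(), ligand_log2fc = numeric(),
                      ligand_padj = numeric(), direction = character(),
                      receiver = character(), receptor = character(),
                      receiver_fraction = numeric(),
                      receiver_mean_expr = numeric())
  if (nrow(ligands) == 0) return(empty)
  rec_genes <- unique(unlist(strsplit(db$receptor, "+", fixed = TRUE)))
  absent <- setdiff(rec_genes, rownames(matrix))
  if (length(absent)) {
    warning("receptor genes absent from the matrix, pairs skipped: ",
            paste(absent, collapse = ", "))
  }
  rec_genes <- setdiff(rec_genes, absent)
  if (!length(rec_genes)) return(empty)
  fr <- fraction_table(matrix, rec_genes, "fraction")
  me <- fraction_table(matrix, rec_genes, "mean_expr")
  receivers <- colnames(fr)

  out <- list()
  for (i in seq_len(nrow(ligands))) {
    lig <- ligands[i, ]
    subunit_hit <- vapply(strsplit(db$ligand, "+", fixed = TRUE),
                          function(s) lig$ligand %in% s, TRUE)
    for (j in which(subunit_hit)) {
      subunits <- strsplit(db$receptor[j], "+", fixed = TRUE)[[1]]
      if (!all(subunits %in% rec_genes)) next
      for (recv in receivers) {
        f <- fr[subunits, recv]
        if (any(is.na(f)) || min(f) < min_fraction) next
        out[[length(out) + 1L]] <- data.frame(
          sender = lig$sender, ligand = lig$ligand,
          interaction = db$interaction[j], ligand_log2fc = lig$log2fc,
          ligand_padj = lig$padj, direction = lig$direction,
          receiver = recv, receptor = db$receptor[j],
          receiver_fraction = min(f),
          receiver_mean_expr = mean(me[subunits, recv]))
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  # one edge per (sender, interaction, receiver): keep the best ligand subunit
  res <- res[order(res$sender, res$interaction, res$receiver, res$ligand_padj), ]
  res <- res[!duplicated(res[, c("sender", "interaction", "receiver")]), ]
  res <- res[order(res$sender, res$ligand, res$receiver, res$receptor), ]
  rownames(res) <- NULL
  res
}

#' Tidy edge table for dot plots
#'
#' Long-format edge table with a `display` flag implementing the
#' "up-regulated ligands only" display convention; both directions remain in
#' the data.
#'
#' @param edges output of [build_edges()].
#' @param direction_filter `"up"`, `"down"` or `"both"`.
#' @return data.frame of edges plus a logical `display` column.
#' @export
edge_table_for_plot <- function(edges, direction_filter = c("up", "down", "both")) {
  direction_filter <- match.arg(direction_filter)
  edges$display <- if (direction_filter == "both") {
    rep(TRUE, nrow(edges))
  } else {
    edges$direction == direction_filter
  }
  edges
}
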