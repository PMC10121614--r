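#' Transcription-factor activity from fold changes
#'
#' Fits one multivariate ordinary-least-squares model: the per-gene log2
#' fold change is regressed on the gene x TF matrix of regulon weights
#' (signed mode of regulation, 0 where a gene is not a target), with an
#' intercept. Each TF's t statistic measures the coordinated shift of its
#' targets, competing against all other regulons at once.
#'
#' @param de a [test_differential_expression()] result.
#' @param net regulon table: `tf`, `target`, `weight` (signed), `confidence`
#'   in `A`-`E`.
#' @param min_confidence confidence levels retained (default the two
#'   highest, `A` and `B`).
#' @return data.frame (`tf`, `coef`, `t_stat`, `pvalue`, `padj`) with fit
#'   metadata (`n_genes`, `df_residual`) in attributes.
#' @export
tf_activity <- function(de, net, min_confidence = c("A", "B")) {
  net <- net[net$confidence %in% min_confidence, , drop = FALSE]
  if (anyDuplicated(net[, c("tf", "target")])) stop("duplicate (tf, target) pairs")
  if (any(!is.finite(net$weight)) || any(net$weight == 0)) {
    stop("regulon weights must be finite and nonzero")
  }
  ok <- !is.na(de$log2fc)
  genes <- de$gene[ok]
  y <- de$log2fc[ok]
  net <- net[net$target %in% genes, , drop = FALSE]
  tfs <- sort(unique(net$tf))
  if (!length(tfs)) stop("no regulon target overlaps the DE universe")
  X <- matrix(0, length(genes), length(tfs), dimnames = list(genes, tfs))
  X[cbind(match(net$target, genes), match(net$tf, tfs))] <- net$weight
  if (length(genes) < length(tfs) + 2) {
    stop("too few genes for the multivariate fit")
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  qr_x <- qr(Xd)
  if (qr_x$rank < ncol(Xd)) {
    drop_cols <- colnames(Xd)[qr_x$pivot[-seq_len(qr_x$rank)]]
    warning("dropping collinear regulons: ", paste(drop_cols, collapse = ", "))
    Xd <- Xd[, setdiff(colnames(Xd), drop_cols), drop = FALSE]
    tfs <- setdiff(tfs, drop_cols)
    qr_x <- qr(Xd)
  }
  fit <- lm.fit(Xd, y)
  df <- length(y) - fit$rank
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  R <- qr.R(fit$qr)
  covu <- chol2inv(R)
  # undo lm.fit's internal pivoting
  piv <- fit$qr$pivot
  se <- sqrt(sigma2 * diag(covu))[order(piv)]
  coefs <- fit$coefficients
  tstat <- coefs / se
  keep <- colnames(Xd) %in% tfs
  p <- 2 * stats::pt(-abs(tstat[keep]), df)
  out <- data.frame(tf = colnames(Xd)[keep], coef = coefs[keep],
                    t_stat = tstat[keep], pvalue = p,
                    padj = adjust_pvalues(p), row.names = NULL)
  out <- out[order(out$pvalue, out$tf), ]
  rownames(out) <- NULL
  attr(out, "n_genes") <- length(y)
  attr(out, "df_residual") <- df
  out
}

#' Equalized top differentially expressed genes per cell type
#'
#' Counts, per cell type, genes with `padj < fdr` and `|log2fc| > lfc_min`;
#' `N` is the median of those counts (lower middle value for even numbers of
#' cell types, so `N` is always an attained count) unless overridden. Each
#' cell type then contributes its `N` top genes ranked by `padj`, then
#' `|log2fc|` descending, then gene name — equalizing statistical power
#' across cell types before over-representation testing.
#'
#' @param de_list named list: cell type -> DE result.
#' @param fdr,lfc_min significance gates for the count.
#' @param top_n optional override of the equalized `N`.
#' @return list with `n`, `sig_counts` and `genes` (named list of
#'   character vectors of length `min(N, genes tested)`).
#' @export
select_top_de <- function(de_list, fdr = 0.01, lfc_min = 1, top_n = NULL) {
  sig_counts <- vapply(de_list, function(de) {
    sum(de$padj < fdr & abs(de$log2fc) > lfc_min, na.rm = TRUE)
  }, 0L)
  if (all(sig_counts == 0) && is.null(top_n)) {
    stop("no cell type has a significant gene; relax fdr/lfc_min or set top_n")
  }
  n <- if (is.null(top_n)) {
    s <- sort(sig_counts)
    s[[ceiling(length(s) / 2)]]   # lower median
  } else {
    top_n
  }
  genes <- lapply(de_list, function(de) {
    de <- de[!is.na(de$padj), , drop = FALSE]
    ord <- order(de$padj, -abs(de$log2fc), de$gene)
    de$gene[ord][seq_len(min(n, nrow(de)))]
  })
  list(n = n, sig_counts = sig_counts, genes = genes)
}

#' One-tailed over-representation p-value
#'
#' Fisher's exact enrichment test: the hypergeometric upper tail
#' `P(X >= overlap)` of drawing `|selected|` genes from a universe
#' containing `|set intersect universe|` successes.
#'
#' @param selected selected gene list (must lie within `universe`).
#' @param gene_set gene set (intersected with `universe`).
#' @param universe background gene list.
#' @return p-value in `(0, 1]`.
#' @export
ora <- function(selected, gene_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  selected <- unique(selected)
  if (!all(selected %in% universe)) stop("selected genes must lie in the universe")
  set_in <- intersect(unique(gene_set), universe)
  overlap <- length(intersect(selected, set_in))
  stats::phyper(overlap - 1, length(set_in),
                length(universe) - length(set_in), length(selected),
                lower.tail = FALSE)
}

#' Over-representation table across cell types and gene sets
#'
#' @param selected_list named list: cell type -> selected genes.
#' @param gene_sets named list: set name -> genes (e.g. [read_gmt()]).
#' @param universes named list: cell type -> universe (the genes tested in
#'   that cell type's DE).
#' @return data.frame (`cell_type`, `gene_set`, `overlap`, `set_size`,
#'   `selected_size`, `universe_size`, `pvalue`, `padj`); `padj` adjusts
#'   within each cell type.
#' @export
ora_table <- function(selected_list, gene_sets, universes) {
  rows <- list()
  for (tname in names(selected_list)) {
    uni <- unique(universes[[tname]])
    sel <- unique(selected_list[[tname]])
    p <- vapply(gene_sets, function(gs) ora(sel, gs, uni), 0)
    set_in <- vapply(gene_sets, function(gs) length(intersect(unique(gs), uni)), 0L)
    ov <- vapply(gene_sets, function(gs) length(intersect(sel, intersect(gs, uni))), 0L)
    rows[[tname]] <- data.frame(
      cell_type = tname, gene_set = names(gene_sets), overlap = ov,
      set_size = set_in, selected_size = length(sel),
      universe_size = length(uni), pvalue = p,
      padj = adjust_pvalues(p), row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
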