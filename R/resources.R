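#' Synthetic regulon network keyed to a generated dataset
#'
#' Builds a DoRothEA-shaped regulon table over the generator's gene
#' universe: random TFs with disjoint random targets and signed unit
#' weights, plus one planted "active" TF whose targets are drawn from the
#' up-regulated planted DE genes of a chosen cell type, so TF-activity
#' recovery is testable.
#'
#' @param genes gene universe (symbols of the generated matrix).
#' @param truth generator truth (used for the active TF's targets); may be
#'   `NULL` for a purely null network.
#' @param active_cell_type whose planted up-regulated genes seed the active
#'   TF.
#' @param n_tfs number of background TFs.
#' @param targets_per_tf regulon size.
#' @param seed RNG seed.
#' @return data.frame (`tf`, `target`, `weight`, `confidence`); the planted
#'   TF is named `TF_ACTIVE`.
#' @export
synthetic_regulons <- function(genes, truth = NULL,
                               active_cell_type = "neutrophil",
                               n_tfs = 10, targets_per_tf = 20, seed = 1L) {
  set.seed(seed)
  rows <- list()
  pool <- genes
  if (!is.null(truth)) {
    det <- truth$de_table
    up <- det$gene[det$cell_type == active_cell_type & det$lfc > 0]
    up <- utils::head(up, targets_per_tf)
    if (length(up)) {
      rows[["active"]] <- data.frame(tf = "TF_ACTIVE", target = up,
                                     weight = 1, confidence = "A")
      pool <- setdiff(pool, up)
    }
  }
  for (i in seq_len(n_tfs)) {
    tg <- sample(pool, targets_per_tf)
    pool <- setdiff(pool, tg)
    rows[[length(rows) + 1L]] <- data.frame(
      tf = sprintf("TF%02d", i), target = tg,
      weight = sample(c(1, 1, 1, -1), targets_per_tf, replace = TRUE),
      confidence = sample(c("A", "B", "C"), targets_per_tf, replace = TRUE,
                          prob = c(0.5, 0.3, 0.2)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic gene-set collection keyed to a generated dataset
#'
#' Random hallmark-style sets plus one set enriched for a cell type's
#' planted DE genes, so over-representation recovery is testable.
#'
#' @param genes gene universe.
#' @param truth generator truth or `NULL`.
#' @param enriched_cell_type whose planted DE genes seed the enriched set.
#' @param n_sets,set_size collection shape.
#' @param seed RNG seed.
#' @return named list of gene vectors; the planted set is
#'   `SET_PLANTED_DE`.
#' @export
synthetic_gene_sets <- function(genes, truth = NULL,
                                enriched_cell_type = "neutrophil",
                                n_sets = 8, set_size = 30, seed = 1L) {
  set.seed(seed)
  sets <- list()
  if (!is.null(truth)) {
    det <- truth$de_table
    de <- det$gene[det$cell_type == enriched_cell_type]
    de <- utils::head(de, set_size %/% 2)
    filler <- sample(setdiff(genes, de), set_size - length(de))
    sets[["SET_PLANTED_DE"]] <- c(de, filler)
  }
  for (i in seq_len(n_sets)) {
    sets[[sprintf("SET%02d", i)]] <- sample(genes, set_size)
  }
  sets
}

#' Marker panels from generator truth
#'
#' Cell-type-level planted markers as annotation panels for
#' [annotate_clusters()].
#'
#' @param truth generator truth.
#' @return named list: cell type -> marker genes.
#' @export
truth_panels <- function(truth) {
  mt <- truth$marker_table
  mt <- mt[is.na(mt$subcluster), , drop = FALSE]
  split(mt$gene, mt$cell_type)
}
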