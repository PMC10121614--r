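#' Graph-based clustering of cells
#'
#' Median-depth log-normalization, restriction to highly variable genes,
#' PCA on standardized expression (unit variance, values clipped at 10
#' standard deviations), a k-nearest-neighbour graph in PC space and
#' modularity-based Leiden community detection. Deterministic for a fixed
#' seed.
#'
#' @param matrix a QC-filtered `SingleCellExperiment`.
#' @param hvgs character vector of genes to cluster on (subset of the gene
#'   set); defaults to all genes.
#' @param n_pcs,k_neighbors,resolution,seed clustering parameters.
#' @return a `perfuseq_clusters` list: `cells` (data.frame `cell_id`,
#'   `cluster`, `label`), `pca` (cell x PC scores), `params`.
#' @export
cluster_cells <- function(matrix, hvgs = rownames(matrix), n_pcs = 30,
                          k_neighbors = 15, resolution = 1.0, seed = 0L) {
  hvgs <- intersect(hvgs, rownames(matrix))
  if (!length(hvgs)) stop("no clustering genes present in the matrix")
  ln <- lognorm_counts(matrix)
  x <- t(as.matrix(ln[hvgs, , drop = FALSE]))   # cells x genes
  n <- nrow(x)
  if (n_pcs >= n) {
    warning("n_pcs reduced to n_cells - 1")
    n_pcs <- n - 1L
  }
  n_pcs <- min(n_pcs, ncol(x))
  mu <- colMeans(x)
  sd <- sqrt(pmax(colMeans(x^2) - mu^2, 0) * n / max(n - 1, 1))
  sd[sd == 0] <- 1
  x <- sweep(sweep(x, 2, mu), 2, sd, `/`)
  x[x > 10] <- 10
  x[x < -10] <- -10
  ev <- eigen(crossprod(x) / (n - 1), symmetric = TRUE)
  rot <- ev$vectors[, seq_len(n_pcs), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(rot))) {
    piv <- which.max(abs(rot[, j]))
    if (rot[piv, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- x %*% rot
  rownames(scores) <- colnames(matrix)

  g <- .knn_graph(scores, k = min(k_neighbors, n - 1))
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
  cl <- igraph::membership(comm)
  structure(list(
    cells = data.frame(cell_id = colnames(matrix), cluster = as.integer(cl),
                       label = NA_character_),
    pca = scores,
    params = list(n_pcs = n_pcs, k_neighbors = k_neighbors,
                  resolution = resolution, seed = seed, n_hvgs = length(hvgs))
  ), class = "perfuseq_clusters")
}

# symmetrized kNN graph, computed in row blocks to bound memory
.knn_graph <- function(scores, k, block = 512L) {
  n <- nrow(scores)
  sq <- rowSums(scores^2)
  nbr <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, `+`) - 2 * scores[idx, , drop = FALSE] %*% t(scores)
    for (r in seq_along(idx)) {
      d2[r, idx[r]] <- Inf
      nbr[idx[r], ] <- order(d2[r, ])[seq_len(k)]
    }
  }
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nbr)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Annotate clusters with marker panels
#'
#' Scores each cluster against each cell-type marker panel by the mean
#' log-normalized expression of the panel genes over the cluster's cells;
#' the label is the arg-max panel, or `"unassigned"` when the top score is
#' non-positive or tied.
#'
#' @param assignment output of [cluster_cells()].
#' @param matrix the clustered `SingleCellExperiment`.
#' @param panels named list: cell type -> character vector of marker genes.
#' @return `assignment` with labels filled in and a `scores` matrix
#'   (cluster x panel) attached.
#' @export
annotate_clusters <- function(assignment, matrix, panels) {
  ln <- lognorm_counts(matrix)
  panels <- lapply(panels, function(p) {
    miss <- setdiff(p, rownames(ln))
    if (length(miss)) warning("dropping absent panel genes: ",
                              paste(miss, collapse = ", "))
    intersect(p, rownames(ln))
  })
  if (all(lengths(panels) == 0)) stop("no panel gene present in the matrix")
  panels <- panels[lengths(panels) > 0]
  cl <- assignment$cells$cluster
  ids <- sort(unique(cl))
  scores <- sapply(panels, function(p) {
    panel_mean <- Matrix::colMeans(ln[p, , drop = FALSE])
    vapply(ids, function(cid) mean(panel_mean[cl == cid]), 0)
  })
  scores <- matrix(scores, nrow = length(ids),
                   dimnames = list(ids, names(panels)))
  labels <- apply(scores, 1, function(s) {
    top <- max(s)
    if (top <= 0 || sum(s == top) > 1) "unassigned" else names(panels)[which.max(s)]
  })
  assignment$cells$label <- labels[match(cl, ids)]
  assignment$scores <- scores
  assignment
}
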