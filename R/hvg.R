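#' Batch-aware highly variable gene selection
#'
#' Per-batch standardized variance in the style of the "seurat_v3" flavor:
#' within each batch a mean-variance trend is fitted to raw counts by loess
#' in log10-log10 space, counts are standardized against the trend with an
#' upper clip at `sqrt(n_cells)` standard deviations, and the variance of
#' the clipped standardized values is the per-gene score. Genes are then
#' ranked by the number of batches in which they fall in the per-batch top
#' `n_top`, with ties broken by median per-batch rank and then by input
#' order.
#'
#' @param matrix a `SingleCellExperiment`.
#' @param n_top number of genes to return.
#' @param batch_key cell metadata column defining batches (default
#'   `"patient"`).
#' @param span loess span for the mean-variance trend.
#' @return character vector of `n_top` gene symbols, most variable first.
#' @export
select_hvgs <- function(matrix, n_top = 4000, batch_key = "patient",
                        span = 0.3) {
  m <- counts_assay(matrix)
  n_top <- min(n_top, nrow(m))
  batches <- cell_meta_df(matrix)[[batch_key]]
  if (is.null(batches)) stop("batch_key '", batch_key, "' not in cell metadata")
  sizes <- table(batches)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding batches with <2 cells: ", paste(small, collapse = ", "))
  }
  use <- setdiff(names(sizes), small)
  if (!length(use)) stop("no batch with >= 2 cells")

  std_var <- sapply(use, function(b) {
    .standardized_variance(as.matrix(m[, batches == b, drop = FALSE]), span)
  })
  std_var <- matrix(std_var, nrow = nrow(m),
                    dimnames = list(rownames(m), use))
  # rank 1 = most variable; ties keep input order (stable)
  per_batch_rank <- apply(-std_var, 2, rank, ties.method = "first")
  in_top <- colSums(t(per_batch_rank) <= n_top)
  med_rank <- apply(per_batch_rank, 1, stats::median)
  ord <- order(-in_top, med_rank, seq_len(nrow(m)))
  rownames(m)[ord[seq_len(n_top)]]
}

.standardized_variance <- function(x, span) {
  n <- ncol(x)
  mu <- rowMeans(x)
  v <- rowSums((x - mu)^2) / (n - 1)
  out <- numeric(nrow(x))
  pos <- v > 0 & mu > 0
  if (sum(pos) < 10) {
    # degenerate input (near-constant genes): no trend can be fitted;
    # score by raw variance so ties fall back to stable gene order
    return(v)
  }
  fit <- suppressWarnings(
    stats::loess(log10(v[pos]) ~ log10(mu[pos]), span = span, degree = 2,
                 control = stats::loess.control(surface = "direct")))
  sd_exp <- suppressWarnings(
    sqrt(pmax(10^stats::predict(fit, log10(mu[pos])), 1e-12)))
  clip_hi <- mu[pos] + sqrt(n) * sd_exp
  xc <- pmin(x[pos, , drop = FALSE], clip_hi)
  out[pos] <- rowSums((xc - mu[pos])^2) / ((n - 1) * sd_exp^2)
  out
}
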