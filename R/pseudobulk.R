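#' Aggregate cells into patient-level pseudo-bulk samples
#'
#' For each cell type, genes expressed (count > 0) in at least
#' `min_expr_fraction` of that type's cells (pooled over timepoints) are
#' retained, and counts are summed per (cell type, patient, timepoint).
#' Samples with fewer than `min_counts` retained-gene counts or fewer than
#' `min_cells` cells are discarded.
#'
#' @param matrix a `SingleCellExperiment` whose cells carry `cell_type`,
#'   `patient` and `timepoint`.
#' @param min_expr_fraction gene retention rule (default 5 percent).
#' @param min_counts,min_cells sample retention rules.
#' @return a `perfuseq_pseudobulk` list: per cell type, `counts` (retained
#'   gene x sample matrix) and `samples` (data.frame `sample_id`, `patient`,
#'   `timepoint`, `n_cells`, `total_counts`); plus `gene_filter_record`.
#' @export
aggregate_pseudobulk <- function(matrix, min_expr_fraction = 0.05,
                                 min_counts = 1000, min_cells = 10) {
  meta <- cell_meta_df(matrix)
  bad <- is.na(meta$cell_type) | is.na(meta$patient) | is.na(meta$timepoint)
  if (any(bad)) {
    stop("cells missing grouping keys: ",
         paste(utils::head(meta$cell_id[bad], 5), collapse = ", "),
         if (sum(bad) > 5) sprintf(" (and %d more)", sum(bad) - 5))
  }
  m <- counts_assay(matrix)
  out <- list()
  filter_record <- list()
  for (tname in sort(unique(meta$cell_type))) {
    sel <- meta$cell_type == tname
    sub <- m[, sel, drop = FALSE]
    keep_genes <- Matrix::rowSums(sub > 0) >= min_expr_fraction * ncol(sub)
    filter_record[[tname]] <- rownames(sub)[keep_genes]
    sub <- sub[keep_genes, , drop = FALSE]
    grp <- interaction(meta$patient[sel], meta$timepoint[sel], drop = TRUE,
                       sep = "|")
    agg <- sub %*% Matrix::sparse.model.matrix(~ 0 + grp)
    agg <- as.matrix(agg)
    colnames(agg) <- sub("^grp", "", colnames(agg))
    parts <- strsplit(colnames(agg), "|", fixed = TRUE)
    samples <- data.frame(
      sample_id = paste(tname, colnames(agg), sep = "|"),
      patient = vapply(parts, `[`, "", 1),
      timepoint = vapply(parts, `[`, "", 2),
      n_cells = as.integer(table(grp)[colnames(agg)]),
      total_counts = colSums(agg)
    )
    keep <- samples$total_counts >= min_counts & samples$n_cells >= min_cells
    if (any(!keep)) {
      message(sprintf("pseudobulk[%s]: discarded %d/%d samples (<%d counts or <%d cells)",
                      tname, sum(!keep), length(keep), min_counts, min_cells))
    }
    agg <- agg[, keep, drop = FALSE]
    samples <- samples[keep, , drop = FALSE]
    colnames(agg) <- samples$sample_id
    rownames(samples) <- NULL
    out[[tname]] <- list(counts = agg, samples = samples)
  }
  structure(list(cell_types = out, gene_filter_record = filter_record,
                 params = list(min_expr_fraction = min_expr_fraction,
                               min_counts = min_counts, min_cells = min_cells)),
            class = "perfuseq_pseudobulk")
}

#' Median-of-ratios size factors
#'
#' DESeq-style: the per-sample median of count ratios to the per-gene
#' geometric mean, computed over genes with no zero in any sample, then
#' rescaled to geometric mean one. Falls back to total-count ratios (with a
#' warning) when no gene is nonzero everywhere.
#'
#' @param counts gene x sample matrix of nonnegative counts.
#' @return positive numeric vector of per-sample size factors.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("at least two samples are required")
  ref <- rowSums(counts == 0) == 0
  if (!any(ref)) {
    warning("no gene nonzero in all samples; using total-count size factors")
    sf <- colSums(counts)
  } else {
    logc <- log(counts[ref, , drop = FALSE])
    geo <- rowMeans(logc)
    sf <- apply(exp(logc - geo), 2, stats::median)
  }
  sf / exp(mean(log(sf)))
}

#' Negative-binomial Wald test on pseudo-bulk
#'
#' Fits, per gene, a negative-binomial log-linear model of pseudo-bulk
#' counts with `log(size factor)` offsets: intercept + patient indicators
#' (when `paired`) + timepoint. Dispersion is estimated by a
#' degrees-of-freedom-aware moment match: alpha solves
#' `sum((y - mu)^2 / (mu * (1 + alpha * mu))) = residual df` with `mu` from a
#' Poisson fit of the same design (floor 1e-8). By default the match is
#' pooled across genes within mean-quantile bins (`dispersion = "pooled"`),
#' which removes the per-gene estimator noise that makes a plug-in Wald test
#' anticonservative at a handful of residual degrees of freedom;
#' `dispersion = "genewise"` solves per gene instead. The Wald statistic
#' `coef / SE` for the timepoint coefficient is referred to a standard
#' normal, two-sided, and p-values are FDR-adjusted over tested genes.
#'
#' @param table a [aggregate_pseudobulk()] object.
#' @param cell_type which cell type's samples to test.
#' @param contrast length-2 character, numerator first: `c("T1", "T0")`
#'   reports log2 fold changes of T1 over T0.
#' @param paired include patient as a fixed covariate (repeated-measures
#'   design); patients lacking a sample at either level are dropped.
#' @param fdr_method passed to [adjust_pvalues()].
#' @param dispersion `"pooled"` (default) or `"genewise"`.
#' @param n_bins mean-quantile bins for pooled dispersion.
#' @return data.frame with one row per retained gene: `gene`, `base_mean`,
#'   `log2fc`, `se`, `wald_stat`, `pvalue`, `padj`; contrast metadata in
#'   attributes.
#' @export
test_differential_expression <- function(table, cell_type,
                                         contrast = c("T1", "T0"),
                                         paired = TRUE, fdr_method = "BH",
                                         dispersion = c("pooled", "genewise"),
                                         n_bins = 10) {
  dispersion <- match.arg(dispersion)
  ctab <- table$cell_types[[cell_type]]
  if (is.null(ctab)) stop("unknown cell type: ", cell_type)
  samp <- ctab$samples
  keep <- samp$timepoint %in% contrast
  samp <- samp[keep, , drop = FALSE]
  counts <- ctab$counts[, keep, drop = FALSE]
  if (paired) {
    both <- names(which(tapply(samp$timepoint, samp$patient,
                               function(x) all(contrast %in% x))))
    ok <- samp$patient %in% both
    samp <- samp[ok, , drop = FALSE]
    counts <- counts[, ok, drop = FALSE]
  }
  for (lev in contrast) {
    if (sum(samp$timepoint == lev) < 2) {
      stop("fewer than 2 samples at level ", lev)
    }
  }
  sf <- estimate_size_factors(counts)
  tp <- as.numeric(samp$timepoint == contrast[1])
  X <- if (paired) {
    stats::model.matrix(~ factor(patient) + tp, data = cbind(samp, tp = tp))
  } else {
    stats::model.matrix(~ tp)
  }
  coef_idx <- ncol(X)
  off <- log(sf)
  counts <- as.matrix(counts)
  norm_counts <- sweep(counts, 2, sf, `/`)
  base_mean <- rowMeans(norm_counts)

  nonzero <- rowSums(counts) > 0
  mu_fit <- matrix(NA_real_, nrow(counts), ncol(counts))
  mu_fit[nonzero, ] <- t(apply(counts[nonzero, , drop = FALSE], 1,
                               .poisson_mu, design = X, off = off))
  df_res <- ncol(counts) - ncol(X)
  alpha <- rep(NA_real_, nrow(counts))
  if (dispersion == "genewise") {
    alpha[nonzero] <- vapply(which(nonzero), function(i) {
      .pearson_alpha(counts[i, , drop = FALSE],
                     mu_fit[i, , drop = FALSE], df_res)
    }, 0)
  } else {
    idx <- which(nonzero)
    bins <- cut(rank(base_mean[idx], ties.method = "first"),
                breaks = min(n_bins, length(idx)), labels = FALSE)
    for (b in unique(bins)) {
      sel <- idx[bins == b]
      alpha[sel] <- .pearson_alpha(counts[sel, , drop = FALSE],
                                   mu_fit[sel, , drop = FALSE], df_res)
    }
  }
  res <- t(vapply(seq_len(nrow(counts)), function(i) {
    if (!nonzero[i]) return(c(NA_real_, NA_real_, NA_real_))
    .nb_wald_gene(counts[i, ], design = X, off = off, coef_idx = coef_idx,
                  alpha = alpha[i])
  }, numeric(3)))
  out <- data.frame(
    gene = rownames(counts),
    base_mean = base_mean,
    log2fc = res[, 1] / log(2),
    se = res[, 2] / log(2),
    wald_stat = res[, 1] / res[, 2],
    pvalue = res[, 3],
    row.names = NULL
  )
  out$padj <- adjust_pvalues(out$pvalue, method = fdr_method,
                             covariate = out$base_mean)
  attr(out, "contrast") <- contrast
  attr(out, "cell_type") <- cell_type
  attr(out, "design") <- if (paired) "~ patient + timepoint" else "~ timepoint"
  attr(out, "n_samples") <- table(samp$timepoint)
  out
}

.glm_ctrl <- function() stats::glm.control(epsilon = 1e-10, maxit = 50)

.poisson_mu <- function(y, design, off) {
  suppressWarnings(
    stats::glm.fit(design, y, offset = off, family = stats::poisson(),
                   control = .glm_ctrl()))$fitted.values
}

# moment match of the Pearson statistic to its residual df over one or
# several genes (rows of y/mu); returns the floored NB dispersion alpha
.pearson_alpha <- function(y, mu, df_res, floor = 1e-8) {
  n_genes <- nrow(mu)
  y <- as.numeric(y)
  mu <- as.numeric(mu)
  ok <- mu > 1e-12
  y <- y[ok]
  mu <- mu[ok]
  f <- function(a) sum((y - mu)^2 / (mu * (1 + a * mu))) - df_res * n_genes
  if (!is.finite(f(0)) || f(0) <= 0) return(floor)
  upper <- 1
  while (f(upper) > 0 && upper < 1e6) upper <- upper * 10
  max(stats::uniroot(f, c(0, upper), tol = 1e-10)$root, floor)
}

# returns c(log-scale coefficient, SE, two-sided p) or NAs
.nb_wald_gene <- function(y, design, off, coef_idx, alpha) {
  fam <- MASS::negative.binomial(theta = 1 / alpha, link = "log")
  fit <- suppressWarnings(
    stats::glm.fit(design, y, offset = off, family = fam,
                   control = .glm_ctrl()))
  p <- fit$rank
  if (p < ncol(design)) return(c(NA_real_, NA_real_, NA_real_))
  # covariance with dispersion fixed at 1 (classic Wald); respect QR pivoting
  covmat <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  k <- which(fit$qr$pivot[seq_len(p)] == coef_idx)
  beta <- fit$coefficients[coef_idx]
  se <- sqrt(covmat[k, k])
  z <- beta / se
  c(beta, se, 2 * stats::pnorm(-abs(z)))
}

#' Adjust p-values for multiple testing
#'
#' `"BH"` is the Benjamini-Hochberg step-up over tested (non-missing)
#' p-values. `"binned"` is a covariate-weighted variant standing in for
#' independent hypothesis weighting: genes are split into quantile bins of
#' the covariate, each bin gets a weight proportional to its estimated
#' non-null fraction (weights normalized to mean one over tests, so the FDR
#' budget is preserved), and BH is applied to `p / w`. Uniform weights
#' reduce it to plain BH.
#'
#' @param pvalues numeric in `[0, 1]`; `NA`s are propagated.
#' @param method `"BH"` or `"binned"`.
#' @param covariate independent covariate (e.g. base mean), required for
#'   `"binned"`.
#' @param n_bins number of covariate quantile bins.
#' @return adjusted p-values, same length and order as `pvalues`.
#' @export
adjust_pvalues <- function(pvalues, method = c("BH", "binned"),
                           covariate = NULL, n_bins = 5) {
  method <- match.arg(method)
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) stop("p-values must be in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  if (method == "BH") {
    out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
    return(out)
  }
  if (is.null(covariate)) stop("binned weighting needs a covariate")
  if (length(covariate) != length(pvalues)) {
    stop("covariate length does not match p-values")
  }
  p <- pvalues[ok]
  cov <- covariate[ok]
  bins <- if (n_bins < 2) rep(1L, length(p)) else {
    cut(rank(cov, ties.method = "first"), breaks = n_bins, labels = FALSE)
  }
  # per-bin non-null signal: 1 - pi0 with pi0 estimated from p > 0.5
  w_bin <- vapply(seq_len(max(bins)), function(b) {
    pb <- p[bins == b]
    if (!length(pb)) return(1)
    pi0 <- min(1, 2 * mean(pb > 0.5))
    max(1 - pi0, 0.05)
  }, 0)
  w <- w_bin[bins]
  w <- w / mean(w)
  out[ok] <- pmin(stats::p.adjust(pmin(p / w, 1), method = "BH"), 1)
  out
}
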