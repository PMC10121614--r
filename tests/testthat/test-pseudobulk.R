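random_cohort <- function(seed, n_genes = 60, n_cells = 300) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, 4), nrow = n_genes)
  rownames(m) <- sprintf("g%03d", seq_len(n_genes))
  tiny_counts(m,
              patients = sample(c("P1", "P2", "P3"), n_cells, TRUE),
              timepoints = sample(c("T0", "T1"), n_cells, TRUE),
              cell_types = sample(c("A", "B"), n_cells, TRUE))
}

test_that("aggregation equals a brute-force triple loop", {
  sc <- random_cohort(1)
  pb <- aggregate_pseudobulk(sc, min_counts = 0, min_cells = 1)
  m <- as.matrix(counts_assay(sc))
  meta <- cell_meta_df(sc)
  for (tname in c("A", "B")) {
    sel <- meta$cell_type == tname
    expr_frac <- rowMeans(m[, sel] > 0)
    expect_identical(pb$gene_filter_record[[tname]],
                     rownames(m)[expr_frac >= 0.05])
    for (p in unique(meta$patient)) for (tp in c("T0", "T1")) {
      cells <- which(sel & meta$patient == p & meta$timepoint == tp)
      if (!length(cells)) next
      sid <- paste(tname, p, tp, sep = "|")
      oracle <- numeric(nrow(m))
      for (cc in cells) oracle <- oracle + m[, cc]
      got <- pb$cell_types[[tname]]$counts[, sid]
      expect_identical(unname(got),
                       unname(oracle[expr_frac >= 0.05]))
      expect_identical(
        pb$cell_types[[tname]]$samples$n_cells[
          pb$cell_types[[tname]]$samples$sample_id == sid],
        length(cells))
    }
  }
})

test_that("the 5 percent expression rule and sample floors are applied", {
  # gene expressed in 4 of 100 cells of a type -> excluded for that type
  m <- matrix(5, nrow = 3, ncol = 112,
              dimnames = list(c("ubiq1", "ubiq2", "rare"), NULL))
  m["rare", ] <- 0
  m["rare", 1:4] <- 1
  sc <- tiny_counts(m, patients = c(rep("P1", 100), rep("P2", 12)),
                    cell_types = rep("A", 112))
  pb <- aggregate_pseudobulk(sc, min_counts = 0, min_cells = 1)
  expect_identical(pb$gene_filter_record$A, c("ubiq1", "ubiq2", "rare")[
    rowMeans(m > 0) >= 0.05])
  expect_false("rare" %in% pb$gene_filter_record$A)

  # a 9-cell sample is dropped regardless of depth
  m2 <- matrix(6000, nrow = 2, ncol = 19)
  sc2 <- tiny_counts(m2, patients = c(rep("P1", 9), rep("P2", 10)),
                     cell_types = rep("A", 19))
  pb2 <- suppressMessages(aggregate_pseudobulk(sc2))
  expect_identical(pb2$cell_types$A$samples$patient, "P2")

  # cells lacking a grouping key are named in the error
  sc3 <- tiny_counts(matrix(1, 2, 3), cell_types = c("A", NA, "A"))
  expect_error(aggregate_pseudobulk(sc3), "c0002")
})

test_that("size factors follow the median-of-ratios definition", {
  expect_equal(estimate_size_factors(cbind(c(2, 4), c(4, 8))),
               c(1 / sqrt(2), sqrt(2)))
  # sample2 = 2 x sample1 -> factors proportional to (1, 2)
  set.seed(3)
  a <- rpois(50, 20) + 1
  sf <- estimate_size_factors(cbind(a, 2 * a))
  expect_equal(unname(sf[2] / sf[1]), 2)
  # identical samples -> all ones
  expect_equal(unname(estimate_size_factors(cbind(a, a, a))), rep(1, 3))
  # no all-nonzero gene -> total-count fallback with warning
  expect_warning(sf2 <- estimate_size_factors(cbind(c(0, 4), c(3, 0))),
                 "total-count")
  expect_equal(prod(sf2), 1)
})

test_that("a constant gene-wise rescaling leaves DE statistics unchanged", {
  sim <- generate_dataset(bulk_config(31, n_genes = 200, mean_cells = 60,
                                      n_patients = 4))
  pb <- aggregate_pseudobulk(sim$matrix, min_counts = 0, min_cells = 1)
  de1 <- test_differential_expression(pb, "bulk", dispersion = "genewise")
  pb2 <- pb
  g <- de1$gene[which.max(de1$base_mean)]   # high counts: refit slack ~ 1/mu
  pb2$cell_types$bulk$counts[g, ] <- pb2$cell_types$bulk$counts[g, ] * 3
  de2 <- test_differential_expression(pb2, "bulk", dispersion = "genewise")
  # scaling one gene in all samples barely moves the size factors, so the
  # gene's own fold change and p-value are preserved up to the dispersion
  # refit (an NB is not exactly closed under scaling)
  i <- which(de1$gene == g)
  expect_lt(abs(de2$log2fc[i] - de1$log2fc[i]), 1e-3)
  expect_lt(abs(de2$pvalue[i] - de1$pvalue[i]), 5e-3)
})

test_that("swapping contrast levels negates log2fc and keeps p-values", {
  sim <- generate_dataset(bulk_config(23, n_genes = 150, mean_cells = 60,
                                      n_patients = 4))
  pb <- aggregate_pseudobulk(sim$matrix, min_counts = 0, min_cells = 1)
  fwd <- test_differential_expression(pb, "bulk", contrast = c("T1", "T0"))
  rev <- test_differential_expression(pb, "bulk", contrast = c("T0", "T1"))
  ok <- !is.na(fwd$pvalue)
  expect_equal(fwd$log2fc[ok], -rev$log2fc[ok], tolerance = 1e-8)
  expect_equal(fwd$pvalue[ok], rev$pvalue[ok], tolerance = 1e-8)
})

test_that("degenerate genes and designs are handled", {
  sim <- generate_dataset(bulk_config(29, n_genes = 100, mean_cells = 60,
                                      n_patients = 4))
  pb <- aggregate_pseudobulk(sim$matrix, min_counts = 0, min_cells = 1)
  # an all-zero gene reports missing statistics
  pb$cell_types$bulk$counts[3, ] <- 0
  de <- test_differential_expression(pb, "bulk")
  expect_true(is.na(de$pvalue[3]) && is.na(de$log2fc[3]))
  expect_true(all(!is.na(de$pvalue[-3])))
  # padj >= pvalue under BH, and monotone in p
  ok <- !is.na(de$pvalue)
  expect_true(all(de$padj[ok] >= de$pvalue[ok]))
  ord <- order(de$pvalue[ok])
  expect_true(all(diff(de$padj[ok][ord]) >= -1e-12))
  # fewer than two samples per level errors
  one_level <- pb
  keep <- one_level$cell_types$bulk$samples$timepoint == "T0"
  one_level$cell_types$bulk$samples <-
    one_level$cell_types$bulk$samples[keep, ]
  one_level$cell_types$bulk$counts <-
    one_level$cell_types$bulk$counts[, keep]
  expect_error(test_differential_expression(one_level, "bulk"), "fewer than 2")
  expect_error(test_differential_expression(pb, "nope"), "unknown cell type")
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  # missing values propagate without shrinking the tested universe
  p <- c(0.01, NA, 0.04)
  out <- adjust_pvalues(p)
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], p.adjust(p[c(1, 3)], "BH"))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
})

test_that("binned weighting degenerates to BH and validates inputs", {
  set.seed(7)
  p <- runif(200)
  cov <- rnorm(200)
  # under the null the estimated weights are near-flat; with all weights
  # forced equal the procedure IS BH
  out <- adjust_pvalues(p, method = "binned", covariate = cov, n_bins = 1)
  expect_equal(out, p.adjust(p, "BH"))
  expect_error(adjust_pvalues(p, method = "binned", covariate = cov[-1]),
               "length")
  expect_error(adjust_pvalues(p, method = "binned"), "covariate")
})
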