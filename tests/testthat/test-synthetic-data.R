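test_that("generation is deterministic for a fixed config and seed", {
  cfg <- bulk_config(seed = 7, n_genes = 300, mean_cells = 40, n_patients = 2)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(as.matrix(counts_assay(a$matrix)),
                   as.matrix(counts_assay(b$matrix)))
  expect_identical(cell_meta_df(a$matrix), cell_meta_df(b$matrix))
  expect_identical(a$truth, b$truth)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(doublet_rate = 1), "doublet_rate")
  expect_error(sim_config(doublet_rate = -0.1), "doublet_rate")
  expect_error(sim_config(cell_types = default_cell_types()[0, ]), "cell type")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(bulk_config(1, timepoints = "T0",
                           de_spec = data.frame(cell_type = "bulk", n_genes = 5L,
                                                lfc = 1, frac_ligand = 0)),
               "two timepoints")
  rf <- default_receptor_fractions()
  rf$fraction[1] <- 1.5
  expect_error(sim_config(receptor_fraction_spec = rf), "receptor fractions")
})

test_that("empty de_spec gives an empty truth table and no timepoint shift", {
  sim <- generate_dataset(bulk_config(seed = 3, n_genes = 400, mean_cells = 120,
                                      n_patients = 4))
  expect_identical(nrow(sim$truth$de_table), 0L)
  m <- counts_assay(sim$matrix)
  tp <- cell_meta_df(sim$matrix)$timepoint
  mean_t0 <- Matrix::rowMeans(m[, tp == "T0"])
  mean_t1 <- Matrix::rowMeans(m[, tp == "T1"])
  keep <- mean_t0 > 0.5 & mean_t1 > 0.5
  lfc <- log2(mean_t1[keep] / mean_t0[keep])
  # no planted effect: shifts are sampling + patient-libsize noise only
  expect_lt(abs(median(lfc)), 0.35)
})

test_that("library-size multiplier halves a neutrophil-like type's depth", {
  # 0.5x multiplier emulates the low-mRNA majority population
  cfg <- sim_config(
    seed = 11, n_patients = 4,
    cell_types = data.frame(name = c("low_mrna", "other"),
                            mean_cells = c(300, 300),
                            libsize_multiplier = c(0.5, 1)),
    n_genes = 800, marker_spec = empty_marker_spec(),
    de_spec = empty_de_spec(),
    receptor_fraction_spec = default_receptor_fractions()[0, ],
    doublet_rate = 0)
  sim <- generate_dataset(cfg)
  meta <- cell_meta_df(sim$matrix)
  expect_gte(nrow(meta), 2000)
  tot <- Matrix::colSums(counts_assay(sim$matrix))
  ratio <- mean(tot[meta$cell_type == "low_mrna"]) /
    mean(tot[meta$cell_type == "other"])
  expect_lt(abs(ratio - 0.5), 0.05)
})

test_that("counts are NB-overdispersed: variance >= mean for most genes", {
  sim <- generate_dataset(bulk_config(seed = 5, n_genes = 600,
                                      mean_cells = 150, n_patients = 1,
                                      patient_libsize_sigma = 0))
  m <- as.matrix(counts_assay(sim$matrix))
  expect_gte(ncol(m), 200)
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  keep <- mu > 0.2
  expect_gte(mean(v[keep] >= mu[keep]), 0.95)
})

test_that("planted log2 fold changes are recovered by pseudo-bulk means", {
  de_spec <- data.frame(cell_type = "bulk", n_genes = c(30L, 30L),
                        lfc = c(1.5, -1.5), frac_ligand = 0)
  sim <- generate_dataset(bulk_config(seed = 9, mean_cells = 300,
                                      de_spec = de_spec))
  m <- counts_assay(sim$matrix)
  meta <- cell_meta_df(sim$matrix)
  grp <- paste(meta$patient, meta$timepoint)
  pb <- sapply(split(seq_len(ncol(m)), grp),
               function(ix) Matrix::rowSums(m[, ix, drop = FALSE]))
  cpm <- sweep(pb, 2, colSums(pb) / 1e6, `/`)
  t1 <- grepl("T1$", colnames(cpm))
  emp_lfc <- log2(rowMeans(cpm[, t1]) / rowMeans(cpm[, !t1]))
  det <- sim$truth$de_table
  expect_true(all(abs(emp_lfc[det$gene] - det$lfc) < 0.3))
})

test_that("doublet injection follows the floor(n x rate) contract", {
  sim <- generate_dataset(bulk_config(seed = 2, n_genes = 100,
                                      mean_cells = 125, n_patients = 4))
  mat <- sim$matrix
  n <- ncol(mat)

  res0 <- inject_doublets(mat, 0, seed = 1)
  expect_identical(ncol(res0$matrix), n)
  expect_identical(res0$doublet_ids, character())

  expect_error(inject_doublets(mat, 1), "rate")

  mat1000 <- mat[, seq_len(1000)]
  res <- inject_doublets(mat1000, 0.05, seed = 3)
  expect_identical(length(res$doublet_ids), 50L)
  expect_identical(ncol(res$matrix), 1050L)
  expect_true(all(res$doublet_ids %in% colnames(res$matrix)))
  # each doublet is an element-wise sum of two existing cells: its total
  # must match the sum of two parents drawn from the same sample, and the
  # doublet profile must dominate neither parent (sum property spot check)
  dbl_meta <- cell_meta_df(res$matrix)
  expect_true(all(dbl_meta$is_doublet[dbl_meta$cell_id %in% res$doublet_ids]))
})

test_that("a forced doublet equals the element-wise sum of its parents", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3)
  sc <- tiny_counts(m)
  res <- inject_doublets(sc, 0.5, seed = 1)   # floor(2 * 0.5) = 1 doublet
  expect_identical(length(res$doublet_ids), 1L)
  dbl <- as.matrix(counts_assay(res$matrix))[, res$doublet_ids]
  expect_identical(unname(dbl), c(1 + 4, 2 + 5, 3 + 6))
})

test_that("planted truth is internally consistent", {
  sim <- default_sim()
  truth <- sim$truth
  # every planted edge's ligand is a DE gene of its sender
  de_key <- paste(truth$de_table$cell_type, truth$de_table$gene)
  expect_true(all(paste(truth$planted_edges$sender,
                        truth$planted_edges$ligand) %in% de_key))
  # every doublet id exists in the matrix
  expect_true(all(truth$doublet_ids %in% colnames(sim$matrix)))
  # planted genes never mitochondrial
  gm <- gene_meta_df(sim$matrix)
  planted <- c(truth$de_table$gene, truth$marker_table$gene)
  expect_false(any(gm$is_mito[match(planted, gm$symbol)]))
})
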