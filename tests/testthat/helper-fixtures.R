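# shared fixtures and tiny constructors; everything is generated in code

.fixtures <- new.env(parent = emptyenv())

# default-world cohort: 8 patients x T0/T1, ~8000 cells, cached per run
default_sim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$sim <- generate_dataset(sim_config(seed = 42))
  }
  .fixtures$sim
}

default_filtered <- function() {
  if (is.null(.fixtures$filtered)) {
    .fixtures$filtered <- suppressMessages(
      remove_doublets(filter_cells(default_sim()$matrix)))
  }
  .fixtures$filtered
}

empty_marker_spec <- function() {
  data.frame(cell_type = character(), subcluster = character(),
             prop = numeric(), n_markers = integer(), lfc = numeric())
}

empty_de_spec <- function() {
  data.frame(cell_type = character(), n_genes = integer(), lfc = numeric(),
             frac_ligand = numeric())
}

# one homogeneous population, no planted structure unless asked for
bulk_config <- function(seed, n_genes = 2000, mean_cells = 150,
                        n_patients = 8, de_spec = empty_de_spec(), ...) {
  sim_config(
    seed = seed, n_patients = n_patients,
    cell_types = data.frame(name = "bulk", mean_cells = mean_cells,
                            libsize_multiplier = 1),
    n_genes = n_genes, marker_spec = empty_marker_spec(), de_spec = de_spec,
    receptor_fraction_spec = default_receptor_fractions()[0, ],
    doublet_rate = 0, ...)
}

# hand-built container from a dense matrix
tiny_counts <- function(mat, patients = NULL, timepoints = NULL,
                        cell_types = NULL) {
  n <- ncol(mat)
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%03d", seq_len(nrow(mat)))
  cm <- data.frame(
    cell_id = sprintf("c%04d", seq_len(n)),
    patient = if (is.null(patients)) rep("P1", n) else patients,
    timepoint = if (is.null(timepoints)) rep("T0", n) else timepoints)
  if (!is.null(cell_types)) cm$cell_type <- cell_types
  cell_counts(mat, cm)
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

edge_key <- function(d) paste(d$sender, d$interaction, d$receiver)

# writes counts + panels + LR db + regulons + GMT for run_pipeline()
write_pipeline_inputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts_dir <- file.path(dir, "counts")
  write_counts(sim$matrix, counts_dir)
  panels <- truth_panels(sim$truth)
  pf <- file.path(dir, "panels.tsv")
  write.table(data.frame(cell_type = rep(names(panels), lengths(panels)),
                         gene = unlist(panels, use.names = FALSE)),
              pf, sep = "\t", quote = FALSE, row.names = FALSE)
  lrf <- file.path(dir, "lr_db.tsv")
  write.table(default_lr_pairs(), lrf, sep = "\t", quote = FALSE,
              row.names = FALSE)
  rf <- file.path(dir, "regulons.tsv")
  write.table(synthetic_regulons(rownames(sim$matrix), sim$truth, seed = 1),
              rf, sep = "\t", quote = FALSE, row.names = FALSE)
  gf <- file.path(dir, "gene_sets.gmt")
  write_gmt(synthetic_gene_sets(rownames(sim$matrix), sim$truth, seed = 1), gf)
  list(counts = counts_dir, panels = pf, lr_db = lrf, regulons = rf,
       gene_sets = gf)
}
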