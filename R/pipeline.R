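#' Run the full analysis pipeline
#'
#' Executes qc -> cluster/annotate -> pseudobulk-de -> markers -> ccc ->
#' enrichment on the counts named in `config$paths`, writing each stage's
#' outputs plus a JSON manifest with input/param/output hashes under
#' `config$paths$out`. A rerun with unchanged inputs skips completed stages
#' via hash matching; a corrupted output is detected and recomputed.
#'
#' @param config a [pipeline_config()] with `paths$counts`, `paths$panels`,
#'   `paths$lr_db`, `paths$regulons`, `paths$gene_sets` and `paths$out` set.
#' @return the run directory, invisibly.
#' @export
run_pipeline <- function(config) {
  p <- config$paths
  for (f in c("counts", "panels", "lr_db", "regulons", "gene_sets", "out")) {
    if (is.null(p[[f]])) stop("config$paths$", f, " must be set")
  }
  out <- p$out
  dir.create(file.path(out, "manifests"), recursive = TRUE, showWarnings = FALSE)
  save_config(config, file.path(out, "config.yaml"))

  counts_files <- file.path(p$counts, c("matrix.mtx", "genes.tsv", "cells.tsv"))
  qc_dir <- file.path(out, "qc", "filtered")
  .run_stage(out, "qc", inputs = counts_files, params = config$qc, fn = function() {
    dir.create(file.path(out, "qc"), recursive = TRUE, showWarnings = FALSE)
    mat <- read_counts(p$counts)
    metrics <- compute_qc_metrics(mat)
    write_tsv(metrics, file.path(out, "qc", "qc_metrics.tsv"))
    mat <- filter_cells(mat, metrics, do.call(qc_thresholds, config$qc))
    mat <- remove_doublets(mat)
    write_tsv(data.frame(cell_id = colnames(mat)),
              file.path(out, "qc", "retained_cells.tsv"))
    write_counts(mat, qc_dir)
    c(file.path(out, "qc", c("qc_metrics.tsv", "retained_cells.tsv")),
      file.path(qc_dir, c("matrix.mtx", "genes.tsv", "cells.tsv")))
  })

  ann_dir <- file.path(out, "cluster", "annotated")
  .run_stage(out, "cluster",
             inputs = c(file.path(qc_dir, "matrix.mtx"), p$panels),
             params = c(config$hvg, config$clustering), fn = function() {
    dir.create(file.path(out, "cluster"), recursive = TRUE, showWarnings = FALSE)
    mat <- read_counts(qc_dir)
    hvgs <- select_hvgs(mat, n_top = config$hvg$n_top,
                        batch_key = config$hvg$batch_key)
    cl <- do.call(cluster_cells, c(list(matrix = mat, hvgs = hvgs),
                                   config$clustering))
    panels_df <- utils::read.delim(p$panels)
    cl <- annotate_clusters(cl, mat, split(panels_df$gene, panels_df$cell_type))
    write_tsv(cl$cells, file.path(out, "cluster", "assignment.tsv"))
    meta <- cell_meta_df(mat)
    meta$cell_type <- cl$cells$label
    mat2 <- cell_counts(counts_assay(mat), meta, gene_meta_df(mat))
    write_counts(mat2, ann_dir)
    c(file.path(out, "cluster", "assignment.tsv"),
      file.path(ann_dir, c("matrix.mtx", "genes.tsv", "cells.tsv")))
  })

  de_dir <- file.path(out, "pseudobulk_de")
  .run_stage(out, "pseudobulk-de",
             inputs = file.path(ann_dir, "matrix.mtx"),
             params = c(config$pseudobulk, config$de), fn = function() {
    mat <- read_counts(ann_dir)
    pb <- do.call(aggregate_pseudobulk,
                  c(list(matrix = mat), config$pseudobulk))
    dir.create(de_dir, recursive = TRUE, showWarnings = FALSE)
    outs <- character()
    for (tname in setdiff(names(pb$cell_types), "unassigned")) {
      de <- tryCatch(
        test_differential_expression(pb, tname,
                                     contrast = config$de$contrast,
                                     paired = config$de$paired,
                                     fdr_method = config$de$fdr_method),
        error = function(e) {
          message("pseudobulk-de[", tname, "] skipped: ", conditionMessage(e))
          NULL
        })
      if (is.null(de)) next
      f <- file.path(de_dir, paste0("de_", tname, ".tsv"))
      dir.create(de_dir, showWarnings = FALSE)
      write_tsv(de, f)
      outs <- c(outs, f)
    }
    outs
  })

  mk_dir <- file.path(out, "markers")
  .run_stage(out, "markers",
             inputs = file.path(ann_dir, "matrix.mtx"),
             params = config$markers, fn = function() {
    mat <- read_counts(ann_dir)
    dir.create(mk_dir, showWarnings = FALSE)
    outs <- character()
    for (tname in config$markers$cell_types) {
      res <- tryCatch({
        sc <- subcluster(mat, tname, n_pcs = config$markers$n_pcs,
                         resolution = config$markers$resolution,
                         seed = config$markers$seed)
        thr <- marker_thresholds(tname)
        sel <- cell_meta_df(mat)$cell_type %in% tname
        call_markers(mat[, sel], sc$cells$cluster,
                     auroc_min = thr$auroc_min, lfc_min = thr$lfc_min)
      }, error = function(e) {
        message("markers[", tname, "] skipped: ", conditionMessage(e))
        NULL
      })
      if (is.null(res)) next
      f <- file.path(mk_dir, paste0("markers_", tname, ".tsv"))
      write_tsv(res, f)
      outs <- c(outs, f)
    }
    outs
  })

  ccc_dir <- file.path(out, "ccc")
  .run_stage(out, "ccc",
             inputs = c(file.path(ann_dir, "matrix.mtx"), p$lr_db),
             params = config$ccc, fn = function() {
    mat <- read_counts(ann_dir)
    db <- read_lr_database(p$lr_db)
    de_list <- .read_de_dir(de_dir)
    ligs <- differential_ligands(de_list, db,
                                 ligand_fdr = config$ccc$ligand_fdr)
    edges <- build_edges(ligs, db, mat,
                         min_fraction = config$ccc$min_fraction)
    dir.create(ccc_dir, showWarnings = FALSE)
    write_tsv(edges, file.path(ccc_dir, "edges.tsv"))
    write_tsv(edge_table_for_plot(edges, "up"),
              file.path(ccc_dir, "edges_plot.tsv"))
    file.path(ccc_dir, c("edges.tsv", "edges_plot.tsv"))
  })

  enr_dir <- file.path(out, "enrichment")
  .run_stage(out, "enrichment",
             inputs = c(p$regulons, p$gene_sets),
             params = config$enrichment, fn = function() {
    net <- read_regulons(p$regulons)
    sets <- read_gmt(p$gene_sets)
    de_list <- .read_de_dir(de_dir)
    dir.create(enr_dir, showWarnings = FALSE)
    outs <- character()
    for (tname in names(de_list)) {
      tf <- tryCatch(
        tf_activity(de_list[[tname]], net,
                    min_confidence = config$enrichment$confidence),
        error = function(e) {
          message("tf[", tname, "] skipped: ", conditionMessage(e))
          NULL
        })
      if (is.null(tf)) next
      f <- file.path(enr_dir, paste0("tf_", tname, ".tsv"))
      write_tsv(tf, f)
      outs <- c(outs, f)
    }
    top <- select_top_de(de_list, fdr = config$enrichment$fdr,
                         lfc_min = config$enrichment$lfc_min,
                         top_n = config$enrichment$top_n)
    universes <- lapply(de_list, function(de) de$gene)
    orares <- ora_table(top$genes, sets, universes)
    f <- file.path(enr_dir, "ora.tsv")
    write_tsv(orares, f)
    c(outs, f)
  })

  invisible(out)
}

.read_de_dir <- function(de_dir) {
  files <- list.files(de_dir, pattern = "^de_.*\\.tsv$", full.names = TRUE)
  de_list <- lapply(files, utils::read.delim)
  names(de_list) <- sub("^de_(.*)\\.tsv$", "\\1", basename(files))
  de_list
}

.hash_files <- function(files) {
  files <- files[file.exists(files)]
  h <- tools::md5sum(files)
  as.list(stats::setNames(unname(h), files))
}

.hash_obj <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, null = "null"), tf)
  unname(tools::md5sum(tf))
}

.run_stage <- function(out, stage, inputs, params, fn) {
  manifest_path <- file.path(out, "manifests", paste0(stage, ".json"))
  in_hash <- .hash_files(inputs)
  par_hash <- .hash_obj(params)
  if (file.exists(manifest_path)) {
    man <- jsonlite::read_json(manifest_path)
    outputs_ok <- length(man$outputs) &&
      all(vapply(names(man$outputs), function(f) {
        file.exists(f) && identical(unname(tools::md5sum(f))[[1]],
                                    man$outputs[[f]])
      }, TRUE))
    if (identical(man$inputs, in_hash) &&
        identical(man$params_hash, par_hash) && outputs_ok) {
      message("stage ", stage, ": up to date, skipped")
      return(invisible(NULL))
    }
  }
  message("stage ", stage, ": running")
  outputs <- fn()
  man <- list(stage = stage, inputs = in_hash, params_hash = par_hash,
              outputs = .hash_files(outputs))
  jsonlite::write_json(man, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(outputs)
}
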