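#' Pipeline configuration
#'
#' All tunable constants of the pipeline, defaulting to the study's stated
#' values: the QC triple (250-8000 genes, 1000-100000 transcripts, <30
#' percent mitochondrial), 4000 batch-aware HVGs, the 5 percent pseudo-bulk
#' expression rule with 1000-count / 10-cell sample floors, the 10 percent
#' receptor fraction gate, and FDR < 0.01 with |log2FC| > 1 for the
#' equalized over-representation input.
#'
#' @param ... named overrides of the nested defaults, e.g.
#'   `qc = list(min_genes = 100)`.
#' @return a validated `perfuseq_config` nested list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    qc = list(min_genes = 250, max_genes = 8000, min_counts = 1000,
              max_counts = 100000, max_pct_mito = 30),
    hvg = list(n_top = 4000, batch_key = "patient"),
    clustering = list(n_pcs = 30, k_neighbors = 15, resolution = 1.0,
                      seed = 0L),
    pseudobulk = list(min_expr_fraction = 0.05, min_counts = 1000,
                      min_cells = 10),
    de = list(paired = TRUE, fdr_method = "BH",
              contrast = c("T1", "T0")),
    markers = list(cell_types = c("neutrophil", "mono_mac"),
                   resolution = 0.5, n_pcs = 20, seed = 0L),
    ccc = list(min_fraction = 0.10, ligand_fdr = 0.05),
    enrichment = list(fdr = 0.01, lfc_min = 1, confidence = c("A", "B"),
                      top_n = NULL),
    paths = list(counts = NULL, panels = NULL, lr_db = NULL,
                 regulons = NULL, gene_sets = NULL, out = NULL)
  )
  cfg <- .merge_config(defaults, list(...), path = "")
  validate_config(cfg)
  structure(cfg, class = "perfuseq_config")
}

.merge_config <- function(base, override, path) {
  if (!length(override)) return(base)
  unknown <- setdiff(names(override), names(base))
  if (length(unknown)) {
    stop("unknown config key", if (length(unknown) > 1) "s", ": ",
         paste0(path, unknown, collapse = ", "))
  }
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[k] <- list(.merge_config(base[[k]], override[[k]],
                                    paste0(path, k, ".")))
    } else {
      base[k] <- list(override[[k]])   # keeps explicit NULLs
    }
  }
  base
}

validate_config <- function(cfg) {
  chk <- function(ok, field) if (!ok) stop("config field out of range: ", field)
  chk(cfg$qc$min_genes < cfg$qc$max_genes, "qc.min_genes/max_genes")
  chk(cfg$qc$min_counts < cfg$qc$max_counts, "qc.min_counts/max_counts")
  chk(cfg$qc$max_pct_mito > 0 && cfg$qc$max_pct_mito <= 100, "qc.max_pct_mito")
  chk(cfg$hvg$n_top >= 1, "hvg.n_top")
  chk(cfg$pseudobulk$min_expr_fraction >= 0 &&
        cfg$pseudobulk$min_expr_fraction <= 1, "pseudobulk.min_expr_fraction")
  chk(cfg$ccc$min_fraction >= 0 && cfg$ccc$min_fraction <= 1,
      "ccc.min_fraction")
  chk(cfg$ccc$ligand_fdr > 0 && cfg$ccc$ligand_fdr <= 1, "ccc.ligand_fdr")
  chk(cfg$enrichment$fdr > 0 && cfg$enrichment$fdr <= 1, "enrichment.fdr")
  chk(cfg$enrichment$lfc_min >= 0, "enrichment.lfc_min")
  chk(all(cfg$enrichment$confidence %in% c("A", "B", "C", "D", "E")),
      "enrichment.confidence")
  chk(length(cfg$de$contrast) == 2, "de.contrast")
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' Missing fields fall back to the study defaults of [pipeline_config()];
#' unknown keys and out-of-range values are rejected by field name.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return a `perfuseq_config` object.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(pipeline_config())
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(pipeline_config, raw)
}

#' @rdname load_config
#' @param config a `perfuseq_config` object to serialize.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
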