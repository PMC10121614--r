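#' Write a count matrix as MatrixMarket + TSV sidecars
#'
#' Writes `matrix.mtx` (1-based coordinate MatrixMarket, genes x cells),
#' `genes.tsv` and `cells.tsv` into `dir`.
#'
#' @param matrix a `SingleCellExperiment`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(matrix, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(counts_assay(matrix), file.path(dir, "matrix.mtx"))
  utils::write.table(gene_meta_df(matrix), file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cell_meta_df(matrix), file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a count matrix from MatrixMarket + TSV sidecars
#'
#' Validates dimensions against the sidecars, integrality and nonnegativity
#' of the counts and uniqueness of identifiers.
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return a `SingleCellExperiment` (see [cell_counts()]).
#' @export
read_counts <- function(dir) {
  mtx_path <- file.path(dir, "matrix.mtx")
  m <- tryCatch(Matrix::readMM(mtx_path), error = function(e) {
    stop("invalid MatrixMarket file ", mtx_path, ": ", conditionMessage(e))
  })
  genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  cells <- utils::read.delim(file.path(dir, "cells.tsv"),
                             stringsAsFactors = FALSE)
  if (!"symbol" %in% names(genes)) stop("genes.tsv must have a 'symbol' column")
  need <- c("cell_id", "patient", "timepoint")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("cells.tsv missing columns: ", paste(miss, collapse = ", "))
  if (nrow(genes) != nrow(m) || nrow(cells) != ncol(m)) {
    stop(sprintf("dimension mismatch: matrix is %d x %d but sidecars have %d genes, %d cells",
                 nrow(m), ncol(m), nrow(genes), nrow(cells)))
  }
  cells$cell_id <- as.character(cells$cell_id)
  if ("subcluster" %in% names(cells)) {
    cells$subcluster <- as.character(cells$subcluster)
  }
  cell_counts(m, cells, genes)
}

#' Read a ligand-receptor interaction table
#'
#' TSV with columns `interaction`, `ligand`, `receptor` (multi-subunit
#' entries joined by `+`) and optionally `pathway`; the legacy column names
#' `ligand_subunits` / `receptor_subunits` are also accepted.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_lr_database <- function(path) {
  db <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"ligand" %in% names(db) && "ligand_subunits" %in% names(db)) {
    db$ligand <- db$ligand_subunits
  }
  if (!"receptor" %in% names(db) && "receptor_subunits" %in% names(db)) {
    db$receptor <- db$receptor_subunits
  }
  need <- c("interaction", "ligand", "receptor")
  miss <- setdiff(need, names(db))
  if (length(miss)) stop("ligand-receptor table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(db$interaction)) stop("duplicate interaction ids")
  if (any(!nzchar(db$ligand)) || any(!nzchar(db$receptor))) {
    stop("empty ligand or receptor entries")
  }
  if (is.null(db$pathway)) db$pathway <- NA_character_
  db[, c("interaction", "ligand", "receptor", "pathway")]
}

#' Read a regulon network table
#'
#' TSV with columns `tf`, `target`, `confidence` and either a signed
#' numeric `weight` or a `mode` column (`activation` / `repression`,
#' encoded as +1 / -1).
#'
#' @param path TSV path.
#' @return data.frame (`tf`, `target`, `weight`, `confidence`).
#' @export
read_regulons <- function(path) {
  net <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(net$weight)) {
    if (!is.null(net$mode)) {
      net$weight <- ifelse(net$mode %in% c("repression", "-1"), -1, 1)
    } else {
      net$weight <- 1
    }
  }
  need <- c("tf", "target", "weight", "confidence")
  miss <- setdiff(need, names(net))
  if (length(miss)) stop("regulon table missing columns: ",
                         paste(miss, collapse = ", "))
  net[, need]
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (set name, description, then genes, tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(x) x[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1)
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene vectors to write.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(n) {
    paste(c(n, "synthetic", sets[[n]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
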