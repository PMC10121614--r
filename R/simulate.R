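#' Simulation configuration for the synthetic perfusion cohort
#'
#' Describes the generative world the pipeline is tested against: a small
#' cohort of donor organs sampled at the start (`T0`) and end (`T1`) of
#' machine perfusion, with cell types of very unequal abundance, a
#' low-mRNA-content majority population, negative-binomial counts with
#' patient-level library-size effects, planted timepoint differential
#' expression (including ligands), planted cell-type and subcluster markers,
#' controllable mitochondrial fractions and a small doublet fraction.
#'
#' Counts are drawn gene-wise from a negative binomial with
#' `variance = mu + alpha * mu^2`; the per-cell mean is
#' `baseline x patient libsize factor x cell-type multiplier x 2^lfc` for
#' genes carrying a planted effect.
#'
#' @param n_patients number of donors.
#' @param timepoints ordered timepoint labels; a subset of `T0`,`T1`,`T2`.
#' @param cell_types data.frame with `name`, `mean_cells` (expected cells per
#'   patient and timepoint) and `libsize_multiplier` (scales every gene's
#'   mean; 0.5 emulates a neutrophil-like low-mRNA population).
#' @param n_genes total genes, including mitochondrial ones.
#' @param n_mito_genes number of `MT-` prefixed genes.
#' @param marker_spec data.frame with `cell_type`, `subcluster` (`NA` for a
#'   cell-type-level marker block), `prop` (subcluster proportion, `NA` at
#'   type level), `n_markers`, `lfc` (log2 elevation inside the group).
#' @param de_spec data.frame with `cell_type`, `n_genes`, `lfc` (signed log2
#'   fold change applied at `T1` and later), `frac_ligand` (fraction of the
#'   planted genes drawn from the ligand pool of `lr_pairs`).
#' @param lr_pairs ligand-receptor table: `interaction`, `ligand`,
#'   `receptor` (subunits joined by `+`), `pathway`.
#' @param receptor_fraction_spec data.frame (`cell_type`, `gene`,
#'   `fraction`): target detection fraction of a receptor subunit in a cell
#'   type; unlisted pairs fall back to `background_fraction`.
#' @param background_fraction detection fraction of receptor genes outside
#'   planted receivers.
#' @param dispersion NB dispersion alpha (scalar or length-`n_genes`).
#' @param patient_libsize_sigma sd of the lognormal per-patient library-size
#'   multiplier shared by all of a patient's cells.
#' @param doublet_rate fraction of doublets appended, in `[0, 1)`.
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of per-gene
#'   baseline means.
#' @param mito_meanlog,mito_sdlog lognormal parameters of mitochondrial gene
#'   means (their own scale so the percent-MT QC filter is exercisable).
#' @param mito_cell_sigma sd of a per-cell lognormal stress factor applied to
#'   mitochondrial genes only, pushing a tail of cells above the 30% gate.
#' @param marker_baseline,de_baseline,ligand_baseline baseline means
#'   overriding the lognormal draw for planted marker / DE / ligand genes so
#'   planted effects are detectable at pseudo-bulk depth.
#' @param seed integer RNG seed; identical config and seed give bit-identical
#'   output.
#' @return a validated `perfuseq_sim_config` list.
#' @export
sim_config <- function(n_patients = 8,
                       timepoints = c("T0", "T1"),
                       cell_types = default_cell_types(),
                       n_genes = 2000,
                       n_mito_genes = 13,
                       marker_spec = default_marker_spec(cell_types),
                       de_spec = default_de_spec(),
                       lr_pairs = default_lr_pairs(),
                       receptor_fraction_spec = default_receptor_fractions(),
                       background_fraction = 0.01,
                       dispersion = 0.4,
                       patient_libsize_sigma = 0.4,
                       doublet_rate = 0.02,
                       baseline_meanlog = log(0.78),
                       baseline_sdlog = 1.6,
                       mito_meanlog = log(46),
                       mito_sdlog = 0.5,
                       mito_cell_sigma = 0.6,
                       marker_baseline = 0.2,
                       de_baseline = 0.5,
                       ligand_baseline = 1.0,
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "perfuseq_sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1, cfg$n_genes >= 1, cfg$n_mito_genes >= 0)
  if (nrow(cfg$cell_types) == 0) stop("at least one cell type is required")
  if (cfg$n_genes <= cfg$n_mito_genes) stop("n_genes must exceed n_mito_genes")
  if (cfg$doublet_rate < 0 || cfg$doublet_rate >= 1) {
    stop("doublet_rate must be in [0, 1)")
  }
  if (!all(cfg$timepoints %in% c("T0", "T1", "T2"))) {
    stop("timepoints must be a subset of T0/T1/T2")
  }
  if (nrow(cfg$de_spec) > 0 && length(cfg$timepoints) < 2) {
    stop("planted DE requires at least two timepoints")
  }
  if (any(cfg$cell_types$mean_cells < 0) ||
      any(cfg$cell_types$libsize_multiplier <= 0)) {
    stop("cell_types: mean_cells must be >= 0 and libsize_multiplier > 0")
  }
  frs <- cfg$receptor_fraction_spec$fraction
  if (length(frs) && (any(frs < 0) || any(frs > 1))) {
    stop("receptor fractions must lie in [0, 1]")
  }
  if (any(cfg$dispersion < 0)) stop("dispersion must be >= 0")
  stopifnot(cfg$background_fraction >= 0, cfg$background_fraction <= 1)
  invisible(cfg)
}

#' @rdname sim_config
#' @export
default_cell_types <- function() {
  data.frame(
    name = c("neutrophil", "mono_mac", "t_cell", "nk", "b_cell",
             "endothelial", "cholangiocyte", "dc", "plasma", "hepatocyte"),
    mean_cells = c(225, 75, 60, 40, 30, 25, 15, 12, 10, 8),
    libsize_multiplier = c(0.5, rep(1, 9))
  )
}

#' @rdname sim_config
#' @export
default_marker_spec <- function(cell_types = default_cell_types()) {
  if (nrow(cell_types) == 0) {
    return(data.frame(cell_type = character(), subcluster = character(),
                      prop = numeric(), n_markers = integer(), lfc = numeric()))
  }
  type_level <- data.frame(
    cell_type = cell_types$name, subcluster = NA_character_,
    prop = NA_real_, n_markers = 20L, lfc = 3
  )
  sub_level <- data.frame(
    cell_type = "neutrophil",
    subcluster = c("N0", "N1", "N2", "N3"),
    prop = c(0.4, 0.3, 0.2, 0.1),
    n_markers = 15L, lfc = 3
  )
  rbind(type_level, sub_level)
}

#' @rdname sim_config
#' @export
default_de_spec <- function() {
  others <- c("t_cell", "nk", "b_cell", "endothelial")
  rbind(
    data.frame(
      cell_type = c("neutrophil", "neutrophil", "mono_mac", "mono_mac"),
      n_genes = c(20L, 10L, 20L, 10L),
      lfc = c(1.5, -1.5, 1.5, -1.5),
      frac_ligand = c(0.1, 0, 0.15, 0)
    ),
    data.frame(
      cell_type = rep(others, each = 2),
      n_genes = rep(c(20L, 10L), length(others)),
      lfc = rep(c(1.5, -1.5), length(others)),
      frac_ligand = 0
    )
  )
}

#' @rdname sim_config
#' @export
default_lr_pairs <- function() {
  data.frame(
    interaction = c("CXCL8_CXCR1", "CXCL8_CXCR2", "VEGFA_FLT1", "VEGFA_KDR",
                    "SPP1_CD44", "SPP1_ITGAV+ITGB1", "FN1_ITGB1",
                    "CCL3_CCR1", "TGFB1_TGFBR1+TGFBR2"),
    ligand = c("CXCL8", "CXCL8", "VEGFA", "VEGFA", "SPP1", "SPP1", "FN1",
               "CCL3", "TGFB1"),
    receptor = c("CXCR1", "CXCR2", "FLT1", "KDR", "CD44", "ITGAV+ITGB1",
                 "ITGB1", "CCR1", "TGFBR1+TGFBR2"),
    pathway = c("CXCL", "CXCL", "VEGF", "VEGF", "SPP1", "SPP1", "FN1",
                "CCL", "TGFb")
  )
}

#' @rdname sim_config
#' @export
default_receptor_fractions <- function() {
  data.frame(
    cell_type = c("neutrophil", "neutrophil", "endothelial", "endothelial",
                  "t_cell", "nk", "mono_mac", "mono_mac", "cholangiocyte",
                  "mono_mac", "dc", "t_cell", "nk"),
    gene = c("CXCR1", "CXCR2", "FLT1", "KDR",
             "CD44", "CD44", "ITGAV", "ITGB1", "ITGB1",
             "CCR1", "CCR1", "TGFBR1", "TGFBR2"),
    fraction = 0.4
  )
}

# mean of an NB(mu, alpha) whose detection probability P(X > 0) equals f
detection_mean <- function(f, alpha) {
  f <- pmin(f, 0.999)
  if (alpha == 0) return(-log(1 - f))
  ((1 - f)^(-alpha) - 1) / alpha
}

mito_gene_names <- function(n) {
  base <- c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8", "MT-ATP6",
            "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4", "MT-ND5", "MT-ND6",
            "MT-CYB")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("MT-G%02d", seq_len(n - length(base)) + length(base)))
}

# Planted-edge truth: every receptor subunit's target fraction >= 0.2 in the
# receiver. Defaults use 0.4 vs 0.01, keeping truth far from the 10% gate.
TRUTH_EDGE_MIN_FRACTION <- 0.2

#' Generate a synthetic cohort with ground truth
#'
#' Draws a gene x cell count matrix per the configured generative model and
#' returns it together with a complete record of what was planted, the
#' oracle for all downstream recovery tests.
#'
#' @param config a [sim_config()] object.
#' @return list with `matrix` (a `SingleCellExperiment`, see [cell_counts()])
#'   and `truth`, a list of `de_table` (`cell_type`, `gene`, `lfc`,
#'   `is_ligand`), `marker_table` (`cell_type`, `subcluster`, `gene`, `lfc`),
#'   `planted_edges` (`sender`, `ligand`, `interaction`, `receiver`,
#'   `receptor`), `doublet_ids`, and `gene_roles`.
#' @export
generate_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  G <- config$n_genes
  alpha <- rep_len(config$dispersion, G)

  # --- gene universe -------------------------------------------------------
  lr_genes <- unique(c(config$lr_pairs$ligand,
                       unlist(strsplit(config$lr_pairs$receptor, "+", fixed = TRUE))))
  ligand_pool <- unique(config$lr_pairs$ligand)
  receptor_genes <- setdiff(lr_genes, ligand_pool)
  mito <- mito_gene_names(config$n_mito_genes)
  n_filler <- G - length(lr_genes) - length(mito)
  if (n_filler < 0) stop("n_genes too small for the ligand-receptor table")
  filler <- sprintf("GENE%04d", seq_len(n_filler))
  symbols <- c(lr_genes, filler, mito)
  is_mito <- symbols %in% mito

  base_mu <- stats::rlnorm(G, config$baseline_meanlog, config$baseline_sdlog)
  names(base_mu) <- symbols
  base_mu[mito] <- stats::rlnorm(length(mito), config$mito_meanlog, config$mito_sdlog)
  base_mu[ligand_pool] <- config$ligand_baseline
  # receptor genes are driven purely by target detection fractions
  base_mu[receptor_genes] <- detection_mean(config$background_fraction, mean(alpha))

  # --- assign planted marker / DE genes from the filler pool ---------------
  pool <- filler
  take <- function(n) {
    if (n > length(pool)) stop("not enough filler genes for the planted spec")
    got <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    got
  }
  ms <- config$marker_spec
  marker_table <- do.call(rbind, lapply(seq_len(nrow(ms)), function(i) {
    if (ms$n_markers[i] == 0) return(NULL)
    data.frame(cell_type = ms$cell_type[i], subcluster = ms$subcluster[i],
               gene = take(ms$n_markers[i]), lfc = ms$lfc[i])
  }))
  if (is.null(marker_table)) {
    marker_table <- data.frame(cell_type = character(), subcluster = character(),
                               gene = character(), lfc = numeric())
  }
  base_mu[marker_table$gene] <- config$marker_baseline

  ds <- config$de_spec
  ligand_left <- ligand_pool
  de_table <- do.call(rbind, lapply(seq_len(nrow(ds)), function(i) {
    n <- ds$n_genes[i]
    n_lig <- min(round(ds$frac_ligand[i] * n), length(ligand_left))
    ligs <- ligand_left[seq_len(n_lig)]
    ligand_left <<- setdiff(ligand_left, ligs)
    fill <- take(n - n_lig)
    data.frame(cell_type = ds$cell_type[i], gene = c(ligs, fill),
               lfc = ds$lfc[i], is_ligand = c(rep(TRUE, n_lig), rep(FALSE, n - n_lig)))
  }))
  if (is.null(de_table)) {
    de_table <- data.frame(cell_type = character(), gene = character(),
                           lfc = numeric(), is_ligand = logical())
  }
  base_mu[de_table$gene[!de_table$is_ligand]] <- config$de_baseline

  # --- per cell type mean vectors ------------------------------------------
  ct <- config$cell_types
  rf <- config$receptor_fraction_spec
  type_mu <- lapply(seq_len(nrow(ct)), function(i) {
    mu <- base_mu * ct$libsize_multiplier[i]
    hit <- rf[rf$cell_type == ct$name[i] & rf$gene %in% symbols, , drop = FALSE]
    if (nrow(hit)) {
      mu[hit$gene] <- vapply(hit$fraction, detection_mean, 0, alpha = mean(alpha))
    }
    type_marks <- marker_table[marker_table$cell_type == ct$name[i] &
                                 is.na(marker_table$subcluster), , drop = FALSE]
    mu[type_marks$gene] <- mu[type_marks$gene] * 2^type_marks$lfc
    mu
  })
  names(type_mu) <- ct$name

  sub_rows <- ms[!is.na(ms$subcluster), , drop = FALSE]
  subclusters_of <- split(sub_rows, sub_rows$cell_type)

  # --- draw cells -----------------------------------------------------------
  patients <- sprintf("P%d", seq_len(config$n_patients))
  pat_factor <- stats::rlnorm(config$n_patients, 0, config$patient_libsize_sigma)
  names(pat_factor) <- patients

  ii <- list(); jj <- list(); xx <- list()
  meta <- list()
  n_cells_total <- 0L
  blk <- 0L
  for (p in patients) {
    for (tp_i in seq_along(config$timepoints)) {
      tp <- config$timepoints[tp_i]
      for (t_i in seq_len(nrow(ct))) {
        tname <- ct$name[t_i]
        n <- stats::rpois(1, ct$mean_cells[t_i])
        if (n == 0) next
        mu <- type_mu[[tname]]
        if (tp_i >= 2 && nrow(de_table)) {
          det <- de_table[de_table$cell_type == tname, , drop = FALSE]
          mu[det$gene] <- mu[det$gene] * 2^det$lfc
        }
        subs <- subclusters_of[[tname]]
        if (!is.null(subs)) {
          sub_lab <- sample(subs$subcluster, n, replace = TRUE,
                            prob = subs$prop / sum(subs$prop))
        } else {
          sub_lab <- rep(NA_character_, n)
        }
        mu_mat <- matrix(mu * pat_factor[p], nrow = G, ncol = n)
        if (!is.null(subs)) {
          for (s_i in seq_len(nrow(subs))) {
            smk <- marker_table[marker_table$cell_type == tname &
                                  !is.na(marker_table$subcluster) &
                                  marker_table$subcluster == subs$subcluster[s_i], ,
                                drop = FALSE]
            if (!nrow(smk)) next
            cols <- which(sub_lab == subs$subcluster[s_i])
            ridx <- match(smk$gene, symbols)
            mu_mat[ridx, cols] <- mu_mat[ridx, cols] * 2^smk$lfc
          }
        }
        if (any(is_mito) && config$mito_cell_sigma > 0) {
          stress <- stats::rlnorm(n, 0, config$mito_cell_sigma)
          mu_mat[is_mito, ] <- sweep(mu_mat[is_mito, , drop = FALSE], 2, stress, `*`)
        }
        y <- if (all(alpha == 0)) {
          stats::rpois(G * n, lambda = mu_mat)
        } else {
          stats::rnbinom(G * n, size = 1 / pmax(alpha, 1e-12), mu = mu_mat)
        }
        nz <- which(y > 0)
        blk <- blk + 1L
        ii[[blk]] <- (nz - 1L) %% G          # 0-based row indices, col-sorted
        jj[[blk]] <- tabulate((nz - 1L) %/% G + 1L, n)
        xx[[blk]] <- y[nz]
        meta[[blk]] <- data.frame(patient = p, timepoint = tp,
                                  cell_type = tname, subcluster = sub_lab)
        n_cells_total <- n_cells_total + n
      }
    }
  }
  cell_meta <- do.call(rbind, meta)
  cell_meta$cell_id <- sprintf("cell%06d", seq_len(n_cells_total))
  cell_meta$is_doublet <- FALSE
  cell_meta <- cell_meta[, c("cell_id", "patient", "timepoint", "cell_type",
                             "subcluster", "is_doublet")]
  # blocks arrive in column order with rows sorted, so CSC is assembled
  # directly (much cheaper than a triplet conversion at ~1e7 nonzeros)
  counts <- Matrix::sparseMatrix(
    i = unlist(ii, use.names = FALSE),
    p = as.integer(c(0L, cumsum(unlist(jj, use.names = FALSE)))),
    x = as.numeric(unlist(xx, use.names = FALSE)),
    dims = c(G, n_cells_total), index1 = FALSE,
    dimnames = list(symbols, cell_meta$cell_id)
  )
  mat <- cell_counts(counts, cell_meta,
                     data.frame(symbol = symbols, is_mito = is_mito))

  doublet_ids <- character()
  if (config$doublet_rate > 0) {
    dd <- .append_doublets(mat, config$doublet_rate)
    mat <- dd$matrix
    doublet_ids <- dd$doublet_ids
  }

  # --- truth ----------------------------------------------------------------
  planted_edges <- .planted_edge_truth(config, de_table)
  truth <- list(
    de_table = de_table,
    marker_table = marker_table,
    planted_edges = planted_edges,
    doublet_ids = doublet_ids,
    gene_roles = data.frame(
      gene = symbols,
      role = ifelse(symbols %in% mito, "mito",
             ifelse(symbols %in% de_table$gene, "de",
             ifelse(symbols %in% marker_table$gene, "marker",
             ifelse(symbols %in% lr_genes, "lr", "background"))))
    )
  )
  list(matrix = mat, truth = truth)
}

.planted_edge_truth <- function(config, de_table) {
  lr <- config$lr_pairs
  rf <- config$receptor_fraction_spec
  lig_rows <- de_table[de_table$is_ligand, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(lig_rows))) {
    hits <- lr[lr$ligand == lig_rows$gene[i], , drop = FALSE]
    for (j in seq_len(nrow(hits))) {
      subunits <- strsplit(hits$receptor[j], "+", fixed = TRUE)[[1]]
      for (recv in config$cell_types$name) {
        fr <- vapply(subunits, function(g) {
          hit <- rf$fraction[rf$cell_type == recv & rf$gene == g]
          if (length(hit)) hit[1] else config$background_fraction
        }, 0)
        if (min(fr) >= TRUTH_EDGE_MIN_FRACTION) {
          out[[length(out) + 1L]] <- data.frame(
            sender = lig_rows$cell_type[i], ligand = lig_rows$gene[i],
            interaction = hits$interaction[j], receiver = recv,
            receptor = hits$receptor[j])
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sender = character(), ligand = character(),
                      interaction = character(), receiver = character(),
                      receptor = character()))
  }
  do.call(rbind, out)
}

#' Append artificial doublets to a count matrix
#'
#' Each doublet is the element-wise sum of two distinct cells drawn from the
#' same (patient, timepoint) sample, appended as a new column. Stands in for
#' classifier-based doublet detection: the returned ids are the truth labels
#' the QC stage can consume.
#'
#' @param matrix a `SingleCellExperiment` (see [cell_counts()]).
#' @param rate doublet fraction in `[0, 1)`; `floor(n_cells * rate)` doublets
#'   are appended.
#' @param seed RNG seed.
#' @return list with `matrix` (augmented) and `doublet_ids`.
#' @export
inject_doublets <- function(matrix, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  set.seed(seed)
  .append_doublets(matrix, rate)
}

.append_doublets <- function(matrix, rate) {
  n <- ncol(matrix)
  n_dbl <- floor(n * rate)
  if (n_dbl == 0) return(list(matrix = matrix, doublet_ids = character()))
  meta <- cell_meta_df(matrix)
  sample_key <- paste(meta$patient, meta$timepoint, sep = "|")
  first <- sample.int(n, n_dbl, replace = TRUE)
  second <- vapply(first, function(i) {
    peers <- setdiff(which(sample_key == sample_key[i]), i)
    if (!length(peers)) peers <- setdiff(seq_len(n), i)
    if (length(peers) == 1) peers else sample(peers, 1)
  }, 0L)
  cm <- counts_assay(matrix)
  dbl <- cm[, first, drop = FALSE] + cm[, second, drop = FALSE]
  ids <- sprintf("doublet%04d", seq_len(n_dbl))
  colnames(dbl) <- ids
  if (!"is_doublet" %in% names(meta)) meta$is_doublet <- FALSE
  dmeta <- meta[first, , drop = FALSE]
  dmeta$cell_id <- ids
  if ("cell_type" %in% names(dmeta)) dmeta$cell_type <- NA
  if ("subcluster" %in% names(dmeta)) dmeta$subcluster <- NA
  dmeta$is_doublet <- TRUE
  new_meta <- rbind(meta, dmeta)
  rownames(new_meta) <- NULL
  out <- .new_sce(cbind(cm, dbl), new_meta, gene_meta_df(matrix))
  list(matrix = out, doublet_ids = ids)
}
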