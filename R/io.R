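#' Save a sweep set as a samples table with a JSON metadata sidecar
#'
#' The native on-disk format is deliberately plain text so fixtures are
#' inspectable and diff-able: a tab-separated samples table with columns
#' (cell_id, condition, trial_index, sample_index, value) and a JSON
#' sidecar `<path>.json` carrying per-sweep metadata and the schema
#' version.  Units are declared in the sidecar (pA for voltage clamp, mV
#' otherwise).
#'
#' @param sweeps a [sweep_set()] (or plain list of [sweep_record()]s).
#' @param path path of the TSV samples table to write; the sidecar is
#'   written alongside as `paste0(path, ".json")`.
#' @param digits significant digits for sample values (default 10).
#' @return `path`, invisibly.
#' @export
save_sweeps <- function(sweeps, path, digits = 10) {
  if (!inherits(sweeps, "sweep_set")) sweeps <- sweep_set(sweeps)
  meta <- lapply(sweeps, function(s) {
    list(cell_id = s$cell_id,
         modality = s$modality,
         sampling_rate = s$sampling_rate,
         n_samples = length(s$signal),
         holding_potential = s$holding_potential,
         ljp_corrected = s$ljp_corrected,
         condition = s$condition,
         trial_index = s$trial_index,
         stimulus_id = s$stimulus_id,
         units = if (s$modality == "voltage_clamp") "pA" else "mV")
  })
  sidecar <- list(schema_version = 1L, n_sweeps = length(sweeps),
                  sweeps = meta)
  tabs <- lapply(sweeps, function(s) {
    data.frame(cell_id = s$cell_id,
               condition = s$condition,
               trial_index = s$trial_index,
               sample_index = seq_along(s$signal) - 1L,
               value = signif(s$signal, digits),
               stringsAsFactors = FALSE)
  })
  tab <- if (length(tabs)) do.call(rbind, tabs) else
    data.frame(cell_id = character(), condition = character(),
               trial_index = integer(), sample_index = integer(),
               value = numeric())
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a sweep set from disk
#'
#' Reads the native sweep-table format written by [save_sweeps()] (TSV
#' samples table plus JSON sidecar).  Every loaded sweep is revalidated
#' through [sweep_record()]; a sweep violating an invariant (for example a
#' voltage-clamp sweep without a holding potential) is rejected rather
#' than silently repaired.
#'
#' @param path path of the TSV samples table; the sidecar
#'   `paste0(path, ".json")` must exist.
#' @param format input format; only `"sweep_table"` is supported.
#' @return a [sweep_set()].
#' @export
load_sweeps <- function(path, format = "sweep_table") {
  format <- match.arg(format, "sweep_table")
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop("metadata sidecar missing: ", sidecar_path)
  }
  sidecar <- jsonlite::read_json(sidecar_path)
  if (is.null(sidecar$schema_version)) {
    stop("sidecar lacks a schema_version; not a sweep-table sidecar")
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c(cell_id = "character",
                                          condition = "character"),
                           stringsAsFactors = FALSE)
  need <- c("cell_id", "condition", "trial_index", "sample_index", "value")
  if (!all(need %in% names(tab))) {
    stop("samples table must have columns: ", paste(need, collapse = ", "))
  }
  sweeps <- lapply(sidecar$sweeps, function(m) {
    if (is.null(m$sampling_rate)) {
      stop("sweep metadata lacks sampling_rate (schema error)")
    }
    sel <- tab$cell_id == m$cell_id & tab$condition == m$condition &
      tab$trial_index == m$trial_index
    rows <- tab[sel, , drop = FALSE]
    rows <- rows[order(rows$sample_index), , drop = FALSE]
    if (nrow(rows) != m$n_samples) {
      stop("sample count mismatch for sweep ", m$cell_id, "/", m$condition,
           "/", m$trial_index, ": sidecar says ", m$n_samples, ", table has ",
           nrow(rows))
    }
    expected_units <- if (identical(m$modality, "voltage_clamp")) "pA" else "mV"
    if (!is.null(m$units) && !identical(m$units, expected_units)) {
      stop("unit mismatch for sweep ", m$cell_id, ": sidecar declares ",
           m$units, " but modality ", m$modality, " implies ", expected_units)
    }
    sweep_record(cell_id = m$cell_id, modality = m$modality,
                 sampling_rate = m$sampling_rate, signal = rows$value,
                 holding_potential = m$holding_potential,
                 ljp_corrected = isTRUE(m$ljp_corrected),
                 condition = m$condition,
                 trial_index = m$trial_index,
                 stimulus_id = m$stimulus_id)
  })
  sweep_set(sweeps)
}

#' Cells-by-genes expression matrix with cluster labels
#'
#' Container for log(TPM+1) expression values.  Entries must be
#' non-negative and every cell carries exactly one cluster label.
#'
#' @param values numeric matrix, cells in rows, genes in columns, on the
#'   log(TPM+1) scale.
#' @param cluster_labels character vector, one label per cell (row).
#' @param gene_ids unique gene identifiers; defaults to `colnames(values)`.
#' @return an object of class `"expression_matrix"`.
#' @export
expression_matrix <- function(values, cluster_labels,
                              gene_ids = colnames(values)) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("expression values must be non-negative")
  if (length(cluster_labels) != nrow(values)) {
    stop("need exactly one cluster label per cell (row)")
  }
  if (is.null(gene_ids)) stop("gene_ids are required")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (length(gene_ids) != ncol(values)) {
    stop("gene_ids length must match the number of genes (columns)")
  }
  colnames(values) <- gene_ids
  structure(list(values = values,
                 cluster_labels = as.character(cluster_labels),
                 gene_ids = as.character(gene_ids)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix>", nrow(x$values), "cells x", ncol(x$values),
      "genes;", length(unique(x$cluster_labels)), "clusters\n")
  invisible(x)
}

#' Read an expression matrix from dense CSV or MatrixMarket files
#'
#' @param values_path dense CSV (cells x genes, header = gene ids, first
#'   column = cell ids) or a MatrixMarket `.mtx` file.
#' @param clusters_path CSV with columns `cell_id,cluster` in matrix row
#'   order.
#' @param gene_ids required for MTX input (the file carries no names).
#' @return an [expression_matrix()].
#' @export
read_expression <- function(values_path, clusters_path, gene_ids = NULL) {
  clusters <- utils::read.csv(clusters_path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "cluster") %in% names(clusters))) {
    stop("cluster file needs columns cell_id,cluster")
  }
  if (grepl("\\.mtx$", values_path)) {
    if (!requireNamespace("Matrix", quietly = TRUE)) {
      stop("reading MatrixMarket input requires the Matrix package")
    }
    values <- as.matrix(Matrix::readMM(values_path))
    if (is.null(gene_ids)) stop("gene_ids must be supplied for MTX input")
  } else {
    raw <- utils::read.csv(values_path, row.names = 1, check.names = FALSE)
    values <- as.matrix(raw)
    if (is.null(gene_ids)) gene_ids <- colnames(values)
  }
  expression_matrix(values, clusters$cluster, gene_ids)
}
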