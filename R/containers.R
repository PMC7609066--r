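## Lightweight S3 containers. The pipeline operates on cells x genes sparse
## matrices with cell and gene metadata kept alongside, mirroring the shape of
## the on-disk Cell-Ranger convention (barcodes = cells, features = genes).

#' Construct a cell-by-gene count matrix with metadata
#'
#' The raw substrate of the pipeline: non-negative integer UMI counts for
#' `n_cells x n_genes`, with per-cell sample and genotype labels and a
#' per-gene mitochondrial flag.
#'
#' @param values matrix-like, cells in rows, genes in columns; coerced to a
#'   sparse `dgCMatrix`. All entries must be non-negative integers.
#' @param cell_meta data frame with columns `cell_id`, `sample`, `genotype`
#'   (values `"wt"` or `"ko"`), one row per cell, in matrix row order.
#' @param gene_meta data frame with columns `gene` and logical `mito`, one row
#'   per gene, in matrix column order.
#' @return object of class `CountMatrix`: a list with elements `values`,
#'   `cell_meta`, `gene_meta`.
#' @export
count_matrix <- function(values, cell_meta, gene_meta) {
  values <- methods::as(methods::as(values, "CsparseMatrix"), "generalMatrix")
  if (nrow(cell_meta) != nrow(values))
    stopf("cell_meta has %d rows but matrix has %d cells",
          nrow(cell_meta), nrow(values))
  if (nrow(gene_meta) != ncol(values))
    stopf("gene_meta has %d rows but matrix has %d genes",
          nrow(gene_meta), ncol(values))
  for (col in c("cell_id", "sample", "genotype"))
    if (!col %in% names(cell_meta)) stopf("cell_meta lacks column '%s'", col)
  for (col in c("gene", "mito"))
    if (!col %in% names(gene_meta)) stopf("gene_meta lacks column '%s'", col)
  if (anyDuplicated(cell_meta$cell_id))
    stopf("duplicate cell ids: %s",
          paste(unique(cell_meta$cell_id[duplicated(cell_meta$cell_id)]),
                collapse = ", "))
  if (anyDuplicated(gene_meta$gene))
    stopf("duplicate gene symbols: %s",
          paste(unique(gene_meta$gene[duplicated(gene_meta$gene)]),
                collapse = ", "))
  bad <- setdiff(unique(cell_meta$genotype), c("wt", "ko"))
  if (length(bad))
    stopf("genotype must be 'wt' or 'ko'; found: %s", paste(bad, collapse = ", "))
  if (any(values@x < 0)) stopf("counts must be non-negative")
  if (any(values@x != round(values@x))) stopf("counts must be integers")
  rownames(values) <- cell_meta$cell_id
  colnames(values) <- gene_meta$gene
  structure(list(values = values,
                 cell_meta = as.data.frame(cell_meta, stringsAsFactors = FALSE),
                 gene_meta = as.data.frame(gene_meta, stringsAsFactors = FALSE)),
            class = "CountMatrix")
}

#' @export
dim.CountMatrix <- function(x) dim(x$values)

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d cells x %d genes (%d wt, %d ko; %d mito genes)\n",
              nrow(x$values), ncol(x$values),
              sum(x$cell_meta$genotype == "wt"),
              sum(x$cell_meta$genotype == "ko"),
              sum(x$gene_meta$mito)))
  invisible(x)
}

new_normalized_matrix <- function(values, cell_meta, gene_meta, scale_factor,
                                  n_umi, counts = NULL, kind = "cells") {
  structure(list(values = values, cell_meta = cell_meta, gene_meta = gene_meta,
                 scale_factor = scale_factor, n_umi = n_umi, counts = counts,
                 kind = kind),
            class = "NormalizedMatrix")
}

#' @export
dim.NormalizedMatrix <- function(x) dim(x$values)

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix (%s): %d x %d, scale factor %g\n",
              x$kind, nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

#' Construct a spot-by-gene spatial count matrix
#'
#' @param values spots x genes counts (coerced sparse).
#' @param spot_meta data frame with columns `spot_id`, `x`, `y`, `sample`,
#'   `genotype`, one row per spot.
#' @param gene_meta data frame with column `gene`.
#' @return object of class `SpotMatrix`.
#' @export
spot_matrix <- function(values, spot_meta, gene_meta) {
  values <- methods::as(methods::as(values, "CsparseMatrix"), "generalMatrix")
  for (col in c("spot_id", "x", "y", "sample", "genotype"))
    if (!col %in% names(spot_meta)) stopf("spot_meta lacks column '%s'", col)
  if (nrow(spot_meta) != nrow(values))
    stopf("spot_meta has %d rows but matrix has %d spots",
          nrow(spot_meta), nrow(values))
  if (nrow(gene_meta) != ncol(values))
    stopf("gene_meta has %d rows but matrix has %d genes",
          nrow(gene_meta), ncol(values))
  pos <- paste(spot_meta$sample, spot_meta$x, spot_meta$y)
  if (anyDuplicated(pos)) stopf("duplicate spot positions within a sample")
  if (any(values@x < 0)) stopf("spot counts must be non-negative")
  rownames(values) <- spot_meta$spot_id
  colnames(values) <- gene_meta$gene
  structure(list(values = values, spot_meta = spot_meta, gene_meta = gene_meta),
            class = "SpotMatrix")
}

#' @export
dim.SpotMatrix <- function(x) dim(x$values)

#' @export
print.SpotMatrix <- function(x, ...) {
  cat(sprintf("SpotMatrix: %d spots x %d genes, %d sample(s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$spot_meta$sample))))
  invisible(x)
}
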