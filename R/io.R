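## Readers for the Cell-Ranger-style Matrix Market triplet layout and for
## dense TSV count tables.

#' Read a Matrix Market triplet count matrix with barcodes and features
#'
#' Expects the Cell Ranger convention: the matrix is genes (features) in rows
#' and cells (barcodes) in columns; it is transposed to cells x genes on read.
#'
#' @param matrix_path path to the `.mtx` file.
#' @param barcodes_path one barcode (cell id) per line.
#' @param features_path one gene symbol per line (first column used if the
#'   file is tab-separated).
#' @param cell_meta data frame or TSV path with columns `cell_id`, `sample`,
#'   `genotype` covering every barcode.
#' @param mito_prefix passed to [flag_mito()].
#' @return a [count_matrix()].
#' @export
read_mtx_triplet <- function(matrix_path, barcodes_path, features_path,
                             cell_meta, mito_prefix = "mt-") {
  for (p in c(matrix_path, barcodes_path, features_path))
    if (!file.exists(p)) stopf("file not found: %s", p)
  m <- Matrix::readMM(matrix_path)
  barcodes <- readLines(barcodes_path)
  feats <- utils::read.delim(features_path, header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  if (length(feats) != nrow(m))
    stopf("%s: matrix declares %d features but %s has %d lines",
          matrix_path, nrow(m), features_path, length(feats))
  if (length(barcodes) != ncol(m))
    stopf("%s: matrix declares %d cells but %s has %d lines",
          matrix_path, ncol(m), barcodes_path, length(barcodes))
  if (any(m@x != round(m@x)))
    stopf("%s: non-integer entries in count matrix", matrix_path)
  if (is.character(cell_meta)) cell_meta <- read_tsv(cell_meta)
  missing <- setdiff(barcodes, cell_meta$cell_id)
  if (length(missing))
    stopf("cell metadata lacks %d barcode(s), e.g. %s", length(missing),
          paste(utils::head(missing, 3), collapse = ", "))
  cell_meta <- cell_meta[match(barcodes, cell_meta$cell_id), , drop = FALSE]
  count_matrix(Matrix::t(m),
               cell_meta = cell_meta,
               gene_meta = data.frame(gene = feats,
                                      mito = flag_mito(feats, mito_prefix),
                                      stringsAsFactors = FALSE))
}

#' Read a dense TSV count table
#'
#' First column must be `cell_id`; remaining columns are gene counts.
#'
#' @param path count table TSV.
#' @param cell_meta data frame or TSV path with `cell_id`, `sample`,
#'   `genotype`.
#' @param mito_prefix passed to [flag_mito()].
#' @return a [count_matrix()].
#' @export
read_counts_tsv <- function(path, cell_meta, mito_prefix = "mt-") {
  df <- read_tsv(path)
  if (names(df)[1] != "cell_id") stopf("first column must be 'cell_id'")
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$cell_id
  if (is.character(cell_meta)) cell_meta <- read_tsv(cell_meta)
  cell_meta <- cell_meta[match(df$cell_id, cell_meta$cell_id), , drop = FALSE]
  count_matrix(vals, cell_meta,
               data.frame(gene = colnames(vals),
                          mito = flag_mito(colnames(vals), mito_prefix),
                          stringsAsFactors = FALSE))
}

#' Flag mitochondrial genes by symbol prefix
#'
#' Case-insensitive literal prefix match, the mouse convention being symbols
#' like `mt-Co1`. The prefix includes its hyphen, so `Mterf1` is not flagged.
#'
#' @param gene_symbols character vector.
#' @param prefix literal prefix, default `"mt-"`.
#' @return logical vector.
#' @export
flag_mito <- function(gene_symbols, prefix = "mt-") {
  startsWith(tolower(gene_symbols), tolower(prefix))
}
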