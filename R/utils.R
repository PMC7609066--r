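## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == as.integer(x) && x >= 0

#' Write a data frame as tab-separated text
#'
#' Plain TSV with a header, no quoting and no row names; the on-disk
#' interchange format used by every stage of the pipeline.
#'
#' @param x data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#'
#' @param path file path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to relabeling), about 0 for independent ones.
#' Used throughout the tests to compare recovered clusters with ground truth.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("label vectors differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

## relabel cluster ids as consecutive integers from 0, largest cluster first;
## ties broken by the smallest original label for determinism
relabel_by_size <- function(labels) {
  tab <- table(labels)
  ord <- order(-as.integer(tab), names(tab))
  map <- stats::setNames(seq_along(ord) - 1L, names(tab)[ord])
  unname(map[as.character(labels)])
}
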