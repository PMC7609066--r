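## Over-representation of gene lists against gene-set collections:
## hypergeometric upper-tail p-values, Benjamini-Hochberg q-values, a fold
## enrichment ("odds of overlapped genes to genes in the gene set"), and the
## filter set p < 0.05, q <= 0.25, odds >= 4, overlap > 2.

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Harmonize gene sets against a universe
#'
#' Deduplicates and intersects every set with the universe (the genes that
#' could have been detected, i.e. those present in the expression matrix
#' after QC).
#'
#' @param sets named list of gene vectors (e.g. from [read_gmt()]).
#' @param universe character vector of gene symbols.
#' @return object of class `geneset_collection`.
#' @export
geneset_collection <- function(sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stopf("empty universe")
  if (length(sets) == 0) stopf("empty gene-set collection")
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  structure(list(sets = sets, universe = universe),
            class = "geneset_collection")
}

#' Over-representation of a query gene list in a collection
#'
#' For each set: overlap k between query and set, hypergeometric upper-tail
#' p = P(X >= k) (with P(X >= 0) = 1), BH q-value across the collection, and
#' fold enrichment odds = (k/n)/(K/N) (alternatively k/K). The pass flag
#' applies `p < p_max`, the q filter, `odds >= odds_min` and
#' `k > min_overlap`.
#'
#' @param query character vector of genes; symbols outside the universe are
#'   dropped with a warning.
#' @param collection a [geneset_collection()].
#' @param p_max raw p cutoff (default 0.05).
#' @param q_max q cutoff (default 0.25).
#' @param q_dir `"le"` filters q <= q_max (default); `"gt"` selects q > q_max,
#'   the literal reading of the source convention.
#' @param odds_min minimum fold enrichment (default 4).
#' @param min_overlap overlap must be strictly greater than this (default 2).
#' @param odds_def `"fold"` for (k/n)/(K/N) or `"k_over_K"`.
#' @return data frame: set, K, n, N, k, odds, p, q, pass.
#' @export
overlap_enrichment <- function(query, collection, p_max = 0.05, q_max = 0.25,
                               q_dir = c("le", "gt"), odds_min = 4,
                               min_overlap = 2,
                               odds_def = c("fold", "k_over_K")) {
  q_dir <- match.arg(q_dir)
  odds_def <- match.arg(odds_def)
  if (!inherits(collection, "geneset_collection"))
    stopf("collection must be a geneset_collection")
  universe <- collection$universe
  query <- unique(query)
  if (length(query) == 0) stopf("empty query gene list")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warnf("%d query gene(s) outside the universe dropped", length(outside))
    query <- intersect(query, universe)
    if (length(query) == 0) stopf("no query genes left inside the universe")
  }
  N <- length(universe); n <- length(query)
  res <- do.call(rbind, lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    K <- length(set)
    k <- length(intersect(query, set))
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    odds <- if (odds_def == "fold") {
      if (K == 0) NA_real_ else (k / n) / (K / N)
    } else {
      if (K == 0) NA_real_ else k / K
    }
    data.frame(set = nm, K = K, n = n, N = N, k = k, odds = odds, p = p,
               stringsAsFactors = FALSE)
  }))
  res$q <- stats::p.adjust(res$p, method = "BH")
  q_ok <- if (q_dir == "le") res$q <= q_max else res$q > q_max
  res$pass <- res$p < p_max & q_ok & !is.na(res$odds) &
    res$odds >= odds_min & res$k > min_overlap
  rownames(res) <- NULL
  res
}

#' Per-cluster overlap with a disease gene set
#'
#' For each cluster's gene list (e.g. up-regulated DEGs): overlap count with
#' the disease set, two-sided Fisher exact p on the 2x2 in/out-query by
#' in/out-set table over the universe, BH q across clusters, and display
#' stars (* p < 0.05, ** p < 0.01).
#'
#' @param cluster_gene_lists named list: cluster -> gene vector.
#' @param disease_set character vector of genes.
#' @param universe character vector of gene symbols.
#' @return data frame: cluster, n_genes, k, p, q, stars.
#' @export
disease_geneset_overlap <- function(cluster_gene_lists, disease_set,
                                    universe) {
  universe <- unique(universe)
  disease_set <- intersect(unique(disease_set), universe)
  if (length(disease_set) == 0) stopf("disease set empty after harmonization")
  res <- do.call(rbind, lapply(names(cluster_gene_lists), function(cl) {
    genes <- intersect(unique(cluster_gene_lists[[cl]]), universe)
    k <- length(intersect(genes, disease_set))
    tab <- matrix(c(k, length(genes) - k,
                    length(disease_set) - k,
                    length(universe) - length(genes) -
                      length(disease_set) + k), nrow = 2)
    p <- if (length(genes) == 0) 1 else
      stats::fisher.test(tab, alternative = "two.sided")$p.value
    data.frame(cluster = cl, n_genes = length(genes), k = k, p = p,
               stringsAsFactors = FALSE)
  }))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$stars <- ifelse(res$p < 0.01, "**", ifelse(res$p < 0.05, "*", ""))
  rownames(res) <- NULL
  res
}
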