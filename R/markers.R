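## Marker detection, genotype differential expression, and the annotation /
## uniqueness rules. The test is the two-sided Wilcoxon rank-sum with
## tie-corrected normal approximation and continuity correction, switching to
## exact permutation enumeration when both groups have <= 10 observations.
## Log fold changes are natural-log ratios of de-logged means with a +1
## pseudocount. Per-genotype marker p-values are combined by the Tippett
## minimum-p method; adjusted p-values are Bonferroni within the gene family
## tested in a cluster.

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Normal approximation with tie correction and continuity correction;
#' exact permutation enumeration over all group assignments when both group
#' sizes are at most `exact_max` (ties handled, since the enumeration
#' permutes the observed ranks).
#'
#' @param x,y numeric vectors for the two groups.
#' @param exact_max switch to exact enumeration when both sizes <= this.
#' @return p-value in `[0, 1]`.
#' @export
rank_sum_p <- function(x, y, exact_max = 10L) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 < 1 || n2 < 1) stopf("both groups must be non-empty")
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    combs <- utils::combn(n, n1)
    Ws <- colSums(matrix(r[combs], nrow = n1))
    # permutation distribution of W is symmetric about mu, so the two-sided
    # p-value is the mass at least as far from mu as observed
    return(mean(abs(Ws - mu) >= abs(W - mu) - 1e-9))
  }
  s2 <- n1 * n2 / (n * (n - 1)) * (sum(r^2) - n * (n + 1)^2 / 4)
  if (s2 <= 0) return(1)
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(s2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

## vectorised normal-approximation rank-sum over the columns of a dense
## cells x genes matrix; in_mask marks group 1
rank_sum_matrix <- function(M, in_mask) {
  n <- nrow(M)
  n1 <- sum(in_mask); n2 <- n - n1
  ranks <- apply(M, 2, rank)
  W <- colSums(ranks[in_mask, , drop = FALSE])
  mu <- n1 * (n + 1) / 2
  s2 <- n1 * n2 / (n * (n - 1)) * (colSums(ranks^2) - n * (n + 1)^2 / 4)
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(pmax(s2, .Machine$double.eps))
  p <- pmin(1, 2 * stats::pnorm(-abs(z)))
  p[s2 <= 0] <- 1
  p
}

group_logfc <- function(norm_vals, in_mask) {
  mean_in <- Matrix::colMeans(expm1(norm_vals[in_mask, , drop = FALSE]))
  mean_out <- Matrix::colMeans(expm1(norm_vals[!in_mask, , drop = FALSE]))
  log((mean_in + 1) / (mean_out + 1))
}

#' One-vs-rest marker statistics for a single cluster
#'
#' For every gene: natural-log fold change of de-logged means (+1
#' pseudocount), two-sided rank-sum p-value, and the fractions of cells
#' expressing (> 0) inside and outside the cluster.
#'
#' @param norm a `NormalizedMatrix`.
#' @param clusters cluster label per cell.
#' @param cluster the cluster to test.
#' @param cells optional logical/integer subset of cells to use (e.g. one
#'   genotype).
#' @param exact_max passed to the rank-sum test.
#' @return data frame (gene, logFC, p, pct_in, pct_out, untestable). When the
#'   cluster (or its complement) has fewer than 3 cells the records are
#'   flagged `untestable = TRUE` with `NA` statistics.
#' @export
rank_markers_one_vs_rest <- function(norm, clusters, cluster, cells = NULL,
                                     exact_max = 10L) {
  v <- norm$values
  if (length(clusters) != nrow(v))
    stopf("clusters length %d != %d cells", length(clusters), nrow(v))
  if (!is.null(cells)) {
    v <- v[cells, , drop = FALSE]
    clusters <- clusters[cells]
  }
  in_mask <- clusters == cluster
  genes <- norm$gene_meta$gene
  if (sum(in_mask) < 3 || sum(!in_mask) < 3) {
    return(data.frame(gene = genes, logFC = NA_real_, p = NA_real_,
                      pct_in = NA_real_, pct_out = NA_real_,
                      untestable = TRUE, stringsAsFactors = FALSE))
  }
  lfc <- group_logfc(v, in_mask)
  pct_in <- Matrix::colMeans(v[in_mask, , drop = FALSE] > 0)
  pct_out <- Matrix::colMeans(v[!in_mask, , drop = FALSE] > 0)
  if (sum(in_mask) <= exact_max && sum(!in_mask) <= exact_max) {
    M <- as.matrix(v)
    p <- vapply(seq_len(ncol(M)), function(j)
      rank_sum_p(M[in_mask, j], M[!in_mask, j], exact_max), numeric(1))
  } else {
    p <- rank_sum_matrix(as.matrix(v), in_mask)
  }
  data.frame(gene = genes, logFC = lfc, p = p, pct_in = pct_in,
             pct_out = pct_out, untestable = FALSE, stringsAsFactors = FALSE)
}

#' Tippett minimum-p combination
#'
#' Combines k p-values as `1 - (1 - min(p))^k`, the distribution of the
#' minimum of k independent uniform p-values. With k = 1 this is the
#' identity.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return combined p-value.
#' @export
combine_min_p <- function(p) {
  if (length(p) == 0) stopf("empty p-value vector")
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  1 - (1 - min(p))^length(p)
}

#' Conserved cluster markers across genotypes
#'
#' Runs one-vs-rest marker statistics separately within each genotype,
#' combines the per-genotype p-values with [combine_min_p()], and averages the
#' per-genotype log fold changes. Genes expressed in less than `min_fraction`
#' of the cluster's cells in either genotype are dropped. Clusters present in
#' only one genotype are skipped with a warning.
#'
#' @param norm a `NormalizedMatrix` of cells.
#' @param clusters cluster label per cell.
#' @param min_fraction in-cluster expression fraction filter (default 0.1).
#' @param exact_max passed to the rank-sum test.
#' @return data frame with per-genotype columns (`logFC_wt`, `p_wt`,
#'   `pct_in_wt`, ... and the ko equivalents), `avg_logFC`, `p_combined`,
#'   `p_adj` (Bonferroni within the cluster's tested family). The full gene
#'   universe is attached as `attr(, "all_genes")`.
#' @export
conserved_markers <- function(norm, clusters, min_fraction = 0.1,
                              exact_max = 10L) {
  gt <- norm$cell_meta$genotype
  out <- list()
  for (cl in sort(unique(clusters))) {
    present <- unique(gt[clusters == cl])
    if (!all(c("wt", "ko") %in% present)) {
      warnf("cluster %s present in only one genotype; skipped", cl)
      next
    }
    per_gt <- lapply(c(wt = "wt", ko = "ko"), function(g)
      rank_markers_one_vs_rest(norm, clusters, cl, cells = gt == g,
                               exact_max = exact_max))
    if (any(per_gt$wt$untestable) || any(per_gt$ko$untestable)) {
      warnf("cluster %s untestable in at least one genotype; skipped", cl)
      next
    }
    keep <- per_gt$wt$pct_in >= min_fraction & per_gt$ko$pct_in >= min_fraction
    if (!any(keep)) next
    w <- per_gt$wt[keep, ]; k <- per_gt$ko[keep, ]
    p_comb <- 1 - (1 - pmin(w$p, k$p))^2
    df <- data.frame(cluster = cl, gene = w$gene,
                     logFC_wt = w$logFC, p_wt = w$p,
                     pct_in_wt = w$pct_in, pct_out_wt = w$pct_out,
                     logFC_ko = k$logFC, p_ko = k$p,
                     pct_in_ko = k$pct_in, pct_out_ko = k$pct_out,
                     avg_logFC = (w$logFC + k$logFC) / 2,
                     p_combined = p_comb,
                     p_adj = pmin(1, p_comb * sum(keep)),
                     stringsAsFactors = FALSE)
    out[[as.character(cl)]] <- df
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cluster = character(), gene = character())
  rownames(res) <- NULL
  attr(res, "all_genes") <- norm$gene_meta$gene
  res
}

#' Annotate clusters from a key-gene panel
#'
#' A cluster is annotated with a cell type when at least `share` (default
#' 50%) of the type's key genes are canonical markers of the cluster, i.e.
#' pass `avg_logFC > logfc_min` and `p_combined < p_max` in the conserved
#' marker table. The boundary is inclusive. Key genes absent from the
#' expression matrix count as misses and are reported in the `warnings`
#' attribute. All qualifying cell types are reported per cluster.
#'
#' @param markers a [conserved_markers()] table.
#' @param panel data frame (`cell_type`, `gene`) or named list of gene
#'   vectors.
#' @param logfc_min,p_max,share rule thresholds (defaults 0, 0.05, 0.5).
#' @return data frame (cluster, cell_type, n_key, n_hit, fraction,
#'   annotated); missing panel genes in `attr(, "warnings")`.
#' @export
annotate_clusters <- function(markers, panel, logfc_min = 0, p_max = 0.05,
                              share = 0.5) {
  if (is.list(panel) && !is.data.frame(panel))
    panel <- data.frame(cell_type = rep(names(panel), lengths(panel)),
                        gene = unlist(panel, use.names = FALSE),
                        stringsAsFactors = FALSE)
  if (nrow(panel) == 0) stopf("empty key-gene panel")
  if (any(tapply(panel$gene, panel$cell_type, length) == 0))
    stopf("panel has an empty cell-type list")
  all_genes <- attr(markers, "all_genes") %||% unique(markers$gene)
  missing <- sort(unique(panel$gene[!panel$gene %in% all_genes]))
  hits <- markers[markers$avg_logFC > logfc_min &
                    markers$p_combined < p_max, c("cluster", "gene")]
  out <- list()
  for (cl in sort(unique(markers$cluster))) {
    cl_hits <- hits$gene[hits$cluster == cl]
    for (ct in sort(unique(panel$cell_type))) {
      keys <- unique(panel$gene[panel$cell_type == ct])
      n_hit <- sum(keys %in% cl_hits)
      frac <- n_hit / length(keys)
      out[[length(out) + 1L]] <-
        data.frame(cluster = cl, cell_type = ct, n_key = length(keys),
                   n_hit = n_hit, fraction = frac,
                   annotated = frac >= share, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "warnings") <- missing
  res
}

#' Differential expression between genotypes within each cluster
#'
#' Per cluster, every gene is tested ko vs wt by the rank-sum test; adjusted
#' p-values are Bonferroni within the cluster; significance is adjusted
#' p < `p_max`. The log fold change is ko over wt. Clusters lacking 3 cells
#' of either genotype are skipped with a warning.
#'
#' @param norm a `NormalizedMatrix`.
#' @param clusters cluster label per cell.
#' @param p_max significance cutoff on adjusted p (default 0.05).
#' @param exact_max passed to the rank-sum test.
#' @return list with `degs` (cluster, gene, logFC, p, padj, significant,
#'   direction) and `summary` (cluster, n_up, n_down).
#' @export
deg_ko_vs_wt <- function(norm, clusters, p_max = 0.05, exact_max = 10L) {
  gt <- norm$cell_meta$genotype
  genes <- norm$gene_meta$gene
  out <- list(); summ <- list()
  for (cl in sort(unique(clusters))) {
    in_cl <- clusters == cl
    n_ko <- sum(in_cl & gt == "ko"); n_wt <- sum(in_cl & gt == "wt")
    if (n_ko < 3 || n_wt < 3) {
      warnf("cluster %s has <3 cells in a genotype; skipped", cl)
      next
    }
    v <- norm$values[in_cl, , drop = FALSE]
    ko_mask <- gt[in_cl] == "ko"
    lfc <- group_logfc(v, ko_mask)
    if (n_ko <= exact_max && n_wt <= exact_max) {
      M <- as.matrix(v)
      p <- vapply(seq_len(ncol(M)), function(j)
        rank_sum_p(M[ko_mask, j], M[!ko_mask, j], exact_max), numeric(1))
    } else {
      p <- rank_sum_matrix(as.matrix(v), ko_mask)
    }
    padj <- pmin(1, p * length(genes))
    sig <- padj < p_max
    df <- data.frame(cluster = cl, gene = genes, logFC = lfc, p = p,
                     padj = padj, significant = sig,
                     direction = ifelse(lfc > 0, "up",
                                        ifelse(lfc < 0, "down", "none")),
                     stringsAsFactors = FALSE)
    out[[as.character(cl)]] <- df
    summ[[as.character(cl)]] <-
      data.frame(cluster = cl, n_up = sum(sig & lfc > 0),
                 n_down = sum(sig & lfc < 0))
  }
  degs <- if (length(out)) do.call(rbind, out) else
    data.frame(cluster = character(), gene = character())
  summary <- if (length(summ)) do.call(rbind, summ) else
    data.frame(cluster = character(), n_up = integer(), n_down = integer())
  rownames(degs) <- rownames(summary) <- NULL
  list(degs = degs, summary = summary)
}

#' Markers unique to a single cluster
#'
#' A gene is a unique marker of cluster c when it passes
#' `avg_logFC > logfc_min` and `p_adj < p_max` in c and in no other cluster.
#'
#' @param markers a [conserved_markers()] table covering every cluster.
#' @param logfc_min,p_max specificity thresholds (defaults 0.25, 0.05).
#' @return data frame (cluster, gene).
#' @export
unique_markers <- function(markers, logfc_min = 0.25, p_max = 0.05) {
  pass <- markers[markers$avg_logFC > logfc_min & markers$p_adj < p_max,
                  c("cluster", "gene")]
  uni <- pass[pass$gene %in% names(which(table(pass$gene) == 1)), ]
  uni <- uni[order(uni$cluster, uni$gene), ]
  rownames(uni) <- NULL
  uni
}

#' Differentially expressed genes unique to a single cluster
#'
#' A gene is a unique DEG of cluster c when it is significant
#' (`|logFC| > logfc_min_abs`, `padj < p_max`) in c and in no other cluster.
#'
#' @param degs the `degs` table from [deg_ko_vs_wt()] covering every cluster.
#' @param logfc_min_abs,p_max thresholds (defaults 0.2, 0.05).
#' @return data frame (cluster, gene, direction).
#' @export
unique_degs <- function(degs, logfc_min_abs = 0.2, p_max = 0.05) {
  pass <- degs[abs(degs$logFC) > logfc_min_abs & degs$padj < p_max,
               c("cluster", "gene", "direction")]
  uni <- pass[pass$gene %in% names(which(table(pass$gene) == 1)), ]
  uni <- uni[order(uni$cluster, uni$gene), ]
  rownames(uni) <- NULL
  uni
}
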