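## Graph-based clustering: PCA embedding, k-nearest-neighbour graph with
## shared-nearest-neighbour (Jaccard) edge weights, modularity community
## detection at a given resolution. A precomputed embedding can be supplied in
## place of the internal PCA (e.g. an externally integrated embedding).

pca_embed <- function(values, n_pcs) {
  if (n_pcs > min(dim(values)))
    stopf("n_pcs (%d) exceeds min(cells, genes) = %d", n_pcs,
          min(dim(values)))
  pc <- stats::prcomp(values, center = FALSE, scale. = FALSE, rank. = n_pcs)
  emb <- pc$x
  # fix the sign convention so the embedding is reproducible across BLAS
  sgn <- apply(emb, 2, function(col) {
    i <- which.max(abs(col))
    if (col[i] < 0) -1 else 1
  })
  sweep(emb, 2, sgn, "*")
}

knn_indices <- function(emb, k, block = 1024L) {
  n <- nrow(emb)
  if (k >= n) stopf("fewer cells (%d) than neighbors_k + 1 (%d)", n, k + 1)
  sq <- rowSums(emb^2)
  idx <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    d2 <- outer(sq[rows], sq, "+") -
      2 * tcrossprod(emb[rows, , drop = FALSE], emb)
    for (r in seq_along(rows)) {
      d2[r, rows[r]] <- Inf
      # partial ordering with stable ties for determinism
      idx[rows[r], ] <- order(d2[r, ])[seq_len(k)]
    }
  }
  idx
}

snn_graph <- function(emb, neighbors_k = 20, prune = 1 / 15) {
  n <- nrow(emb)
  nn <- knn_indices(emb, neighbors_k)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), neighbors_k),
                            j = as.vector(nn), x = 1, dims = c(n, n))
  A <- A + Matrix::Diagonal(n)        # count self in the neighbourhood
  shared <- Matrix::tcrossprod(A)
  shared <- methods::as(shared, "CsparseMatrix")
  k1 <- neighbors_k + 1
  shared@x <- shared@x / (2 * k1 - shared@x)   # Jaccard on neighbour sets
  shared@x[shared@x < prune] <- 0
  shared <- Matrix::drop0(shared)
  Matrix::diag(shared) <- 0
  g <- igraph::graph_from_adjacency_matrix(shared, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g
}

#' Embed cells and cluster them at one resolution
#'
#' PCA to `n_pcs` components (default 30), k-nearest-neighbour graph with
#' shared-neighbour Jaccard weights, Louvain modularity optimisation at the
#' given resolution. Labels are consecutive integers from 0 ordered by
#' decreasing cluster size; a fixed seed makes the result deterministic.
#'
#' @param scaled a `ScaledMatrix` from [regress_covariate()], or any numeric
#'   cells x features matrix.
#' @param n_pcs number of principal components (default 30). Ignored when
#'   `embedding` is supplied.
#' @param resolution modularity resolution parameter.
#' @param neighbors_k neighbours for the kNN graph (default 20).
#' @param seed RNG seed for the community detection (default 0).
#' @param embedding optional precomputed cells x dims embedding; bypasses PCA.
#' @return integer vector of 0-based cluster labels, one per cell.
#' @export
embed_cluster <- function(scaled, n_pcs = 30, resolution = 0.8,
                          neighbors_k = 20, seed = 0, embedding = NULL) {
  res <- cluster_scan(scaled, resolutions = resolution, n_pcs = n_pcs,
                      neighbors_k = neighbors_k, seed = seed,
                      embedding = embedding)
  res[, 1]
}

#' Cluster the same graph at several resolutions
#'
#' Builds the embedding and SNN graph once and runs community detection at
#' each resolution, the substrate for the clustering-tree resolution
#' heuristic.
#'
#' @inheritParams embed_cluster
#' @param resolutions ascending numeric vector of resolutions.
#' @return integer matrix, cells x resolutions, of 0-based labels; columns
#'   named by resolution.
#' @export
cluster_scan <- function(scaled, resolutions, n_pcs = 30, neighbors_k = 20,
                         seed = 0, embedding = NULL) {
  values <- if (inherits(scaled, "ScaledMatrix")) scaled$values else
    as.matrix(scaled)
  emb <- if (is.null(embedding)) pca_embed(values, n_pcs) else
    as.matrix(embedding)
  g <- snn_graph(emb, neighbors_k)
  out <- matrix(NA_integer_, nrow(emb), length(resolutions),
                dimnames = list(NULL, as.character(resolutions)))
  for (j in seq_along(resolutions)) {
    set.seed(seed + j - 1L)
    comm <- igraph::cluster_louvain(g, resolution = resolutions[j])
    out[, j] <- relabel_by_size(igraph::membership(comm))
  }
  out
}
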