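## Multi-resolution clustering tree and the stable-region / over-clustered
## region resolution-selection heuristic. The tree's edges carry
## "in-proportions": for a cluster at resolution r_{i+1}, the fraction of its
## cells that came from each cluster at resolution r_i.

#' Build a clustering tree across resolutions
#'
#' Cross-tabulates cluster assignments at consecutive resolutions. Each edge
#' from a parent cluster (lower resolution) to a child cluster (next
#' resolution) is weighted by the in-proportion: the fraction of the child's
#' cells coming from that parent. In-proportions over a child's incoming
#' edges sum to 1.
#'
#' @param assignments data frame or matrix: one row per cell, one column per
#'   resolution (column names are the resolutions, ascending). An optional
#'   `cell_id` column is ignored for the cross-tabulation.
#' @return object of class `cluster_tree`: list with `resolutions`, `nodes`
#'   (resolution, cluster, size) and `edges` (res_parent, parent, res_child,
#'   child, n_cells, in_prop).
#' @export
build_cluster_tree <- function(assignments) {
  if (is.list(assignments) && !is.data.frame(assignments)) {
    # list of named label vectors, one per resolution: align by cell id
    ids <- lapply(assignments, names)
    ref <- ids[[1]]
    for (j in seq_along(ids)) {
      miss <- union(setdiff(ref, ids[[j]]), setdiff(ids[[j]], ref))
      if (length(miss))
        stopf("cell sets differ across resolutions; e.g. %s",
              paste(utils::head(miss, 5), collapse = ", "))
    }
    assignments <- as.data.frame(lapply(assignments, function(a) a[ref]))
    names(assignments) <- names(ids)
  }
  df <- as.data.frame(assignments)
  df$cell_id <- NULL
  res <- suppressWarnings(as.numeric(names(df)))
  if (anyNA(res)) stopf("assignment columns must be named by resolution")
  if (length(res) < 1) stopf("need at least one resolution")
  if (is.unsorted(res, strictly = TRUE))
    stopf("resolutions must be strictly ascending")
  if (anyNA(df)) stopf("missing cluster labels in assignments")

  nodes <- do.call(rbind, lapply(seq_along(res), function(j) {
    tab <- table(df[[j]])
    data.frame(resolution = res[j], cluster = names(tab),
               size = as.integer(tab), stringsAsFactors = FALSE)
  }))
  edges <- NULL
  if (length(res) >= 2) {
    edges <- do.call(rbind, lapply(seq_len(length(res) - 1), function(j) {
      tab <- table(parent = df[[j]], child = df[[j + 1]])
      long <- as.data.frame(tab, stringsAsFactors = FALSE)
      long <- long[long$Freq > 0, ]
      child_sizes <- colSums(tab)
      data.frame(res_parent = res[j], parent = long$parent,
                 res_child = res[j + 1], child = long$child,
                 n_cells = long$Freq,
                 in_prop = long$Freq / child_sizes[long$child],
                 stringsAsFactors = FALSE)
    }))
    rownames(edges) <- NULL
  }
  structure(list(resolutions = res, nodes = nodes, edges = edges),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  counts <- vapply(x$resolutions, function(r)
    sum(x$nodes$resolution == r), integer(1))
  cat("cluster_tree over resolutions:",
      paste(sprintf("%g(%d)", x$resolutions, counts), collapse = " "), "\n")
  invisible(x)
}

tree_cluster_counts <- function(tree) {
  vapply(tree$resolutions, function(r)
    sum(tree$nodes$resolution == r), integer(1))
}

## TRUE when the step from resolution i to i+1 is an identity-like one-to-one
## mapping: equal cluster counts, every child dominated by a single parent
## (max in-proportion >= threshold), and those dominant parents all distinct.
step_one_to_one <- function(tree, i, identity_threshold) {
  r1 <- tree$resolutions[i]; r2 <- tree$resolutions[i + 1]
  n1 <- sum(tree$nodes$resolution == r1)
  n2 <- sum(tree$nodes$resolution == r2)
  if (n1 != n2) return(FALSE)
  e <- tree$edges[tree$edges$res_parent == r1, ]
  dom <- vapply(split(e, e$child), function(ec) {
    if (max(ec$in_prop) < identity_threshold) NA_character_
    else ec$parent[which.max(ec$in_prop)]
  }, character(1))
  !anyNA(dom) && !anyDuplicated(dom)
}

#' Find stable resolution regions in a clustering tree
#'
#' A stable region is a maximal run of consecutive resolutions over which the
#' total number of clusters stays constant and no sub-branching occurs: every
#' step inside the run is a one-to-one parent-child mapping (each child takes
#' at least `identity_threshold` of its cells from a single, distinct parent).
#' A single resolution is a degenerate stable region.
#'
#' @param tree a [build_cluster_tree()] result.
#' @param identity_threshold dominant-parent share required to call a step
#'   one-to-one (default 0.9).
#' @return data frame with columns `r_lo`, `r_hi`, `n_clusters`.
#' @export
find_stable_regions <- function(tree, identity_threshold = 0.9) {
  res <- tree$resolutions
  n <- length(res)
  stable_step <- if (n > 1)
    vapply(seq_len(n - 1), step_one_to_one, logical(1),
           tree = tree, identity_threshold = identity_threshold) else logical(0)
  counts <- tree_cluster_counts(tree)
  regions <- list()
  start <- 1L
  for (i in seq_len(n)) {
    extend <- i < n && stable_step[i] && counts[i + 1] == counts[i]
    if (!extend) {
      regions[[length(regions) + 1L]] <-
        data.frame(r_lo = res[start], r_hi = res[i], n_clusters = counts[i])
      start <- i + 1L
    }
  }
  do.call(rbind, regions)
}

#' Locate the onset of over-clustering
#'
#' Over-clustering begins where a genuinely new cluster forms out of multiple
#' parent clusters: a child that is not the main continuation of any parent
#' (it does not receive the plurality of any parent's cells) and that draws at
#' least `low_inprop` of its own cells from at least `min_parents` distinct
#' parents.
#'
#' @param tree a [build_cluster_tree()] result.
#' @param low_inprop minimum in-proportion for a parent to count (default 0.1).
#' @param min_parents minimum number of qualifying parents (default 2).
#' @return the smallest resolution at which this occurs, or `NULL`.
#' @export
find_overclustered_onset <- function(tree, low_inprop = 0.1,
                                     min_parents = 2) {
  res <- tree$resolutions
  if (length(res) < 2) return(NULL)
  for (i in seq_len(length(res) - 1)) {
    e <- tree$edges[tree$edges$res_parent == res[i], ]
    # out-proportions: share of each parent's cells sent to each child
    parent_sizes <- tapply(e$n_cells, e$parent, sum)
    e$out_prop <- e$n_cells / parent_sizes[e$parent]
    main_child <- vapply(split(e, e$parent), function(ep)
      ep$child[which.max(ep$out_prop)], character(1))
    for (ch in unique(e$child)) {
      if (ch %in% main_child) next            # a continuation, not new
      ec <- e[e$child == ch, ]
      if (sum(ec$in_prop >= low_inprop) >= min_parents)
        return(res[i + 1])
    }
  }
  NULL
}

#' Select the working clustering resolution
#'
#' Picks the highest resolution that lies in a stable region situated
#' entirely below the over-clustering onset (all resolutions qualify when no
#' onset exists).
#'
#' @param tree a [build_cluster_tree()] result.
#' @param identity_threshold passed to [find_stable_regions()].
#' @param low_inprop,min_parents passed to [find_overclustered_onset()].
#' @return list of class `region_report`: `stable_regions`,
#'   `overclustered_onset` (or `NULL`), `selected_resolution`, `n_clusters`.
#' @export
select_resolution <- function(tree, identity_threshold = 0.9,
                              low_inprop = 0.1, min_parents = 2) {
  regions <- find_stable_regions(tree, identity_threshold)
  onset <- find_overclustered_onset(tree, low_inprop, min_parents)
  ok <- if (is.null(onset)) rep(TRUE, nrow(regions)) else
    regions$r_hi < onset
  if (!any(ok))
    stopf(paste("no stable region below the over-clustering onset (%g);",
                "widen the resolution grid toward lower values"), onset)
  selected <- max(regions$r_hi[ok])
  n_sel <- regions$n_clusters[regions$r_hi == selected][1]
  structure(list(stable_regions = regions, overclustered_onset = onset,
                 selected_resolution = selected, n_clusters = n_sel),
            class = "region_report")
}

#' @export
print.region_report <- function(x, ...) {
  cat("stable regions:\n")
  print(x$stable_regions)
  cat(sprintf("over-clustering onset: %s\nselected resolution: %g (%d clusters)\n",
              if (is.null(x$overclustered_onset)) "none" else
                format(x$overclustered_onset),
              x$selected_resolution, x$n_clusters))
  invisible(x)
}
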