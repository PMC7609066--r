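# assignments are built by hand so every in-proportion is known exactly

test_that("tree edges carry exact in-proportions from cross-tabulation", {
  # identity step: each child one incoming edge of in_prop 1
  a <- data.frame("0.1" = rep(0:1, each = 50), "0.2" = rep(0:1, each = 50),
                  check.names = FALSE)
  tree <- build_cluster_tree(a)
  expect_equal(nrow(tree$edges), 2L)
  expect_equal(tree$edges$in_prop, c(1, 1))

  # 100-cell cluster splitting 60/40: both children fully from the parent
  b <- data.frame("0.1" = rep(0, 100), "0.2" = rep(c(0, 1), c(60, 40)),
                  check.names = FALSE)
  tb <- build_cluster_tree(b)
  expect_equal(tb$edges$in_prop, c(1, 1))
  expect_equal(sort(tb$nodes$size[tb$nodes$resolution == 0.2]), c(40L, 60L))

  # child drawing 30 cells from parent A and 20 from parent B
  c_ <- data.frame("0.1" = rep(c("A", "B"), c(60, 40)),
                   "0.2" = c(rep("x", 30), rep("z", 30),
                             rep("x", 20), rep("w", 20)),
                   check.names = FALSE)
  tc <- build_cluster_tree(c_)
  ex <- tc$edges[tc$edges$child == "x", ]
  expect_equal(ex$in_prop[order(ex$parent)], c(0.6, 0.4))
  # in-proportions per child always sum to 1
  sums <- tapply(tc$edges$in_prop, tc$edges$child, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("mismatched cell sets across resolutions are an error", {
  expect_error(build_cluster_tree(list("0.1" = c(a = 0, b = 0),
                                       "0.2" = c(a = 0, c = 1))),
               "differ")
})

# helper: assignments with given cluster counts and clean 1:1 or split maps
seq_assignments <- function(counts, n = 120) {
  stopifnot(n %% max(counts) == 0)
  cols <- lapply(counts, function(k) rep(seq_len(k) - 1, each = n / k))
  names(cols) <- sprintf("%.1f", seq(0.1, by = 0.1, length.out = length(counts)))
  as.data.frame(cols, check.names = FALSE)
}

test_that("stable regions are maximal constant-count runs with 1:1 maps", {
  tree <- build_cluster_tree(seq_assignments(c(2, 2, 3, 3, 4)))
  reg <- find_stable_regions(tree)
  expect_equal(reg$r_lo, c(0.1, 0.3, 0.5))
  expect_equal(reg$r_hi, c(0.2, 0.4, 0.5))
  expect_equal(reg$n_clusters, c(2L, 3L, 4L))

  # strictly increasing counts: only degenerate regions
  tree2 <- build_cluster_tree(seq_assignments(c(2, 3, 4)))
  reg2 <- find_stable_regions(tree2)
  expect_equal(reg2$r_lo, reg2$r_hi)

  # single resolution: one degenerate region
  tree3 <- build_cluster_tree(data.frame("0.5" = rep(0:2, each = 10),
                                         check.names = FALSE))
  reg3 <- find_stable_regions(tree3)
  expect_equal(reg3, data.frame(r_lo = 0.5, r_hi = 0.5, n_clusters = 3L))
})

test_that("equal counts without a 1:1 map do not extend a stable region", {
  # two clusters swap half their cells: counts constant but not one-to-one
  a <- data.frame("0.1" = rep(0:1, each = 50),
                  "0.2" = c(rep(0, 25), rep(1, 25), rep(1, 25), rep(0, 25)),
                  check.names = FALSE)
  reg <- find_stable_regions(build_cluster_tree(a))
  expect_equal(nrow(reg), 2L)
})

test_that("over-clustering onset detects new clusters with multiple parents", {
  # child "n" takes 50/50 from two parents that both keep their majorities
  a <- data.frame("0.1" = rep(c("A", "B"), each = 60),
                  "0.2" = c(rep("a", 40), rep("n", 20),
                            rep("b", 40), rep("n", 20)),
                  check.names = FALSE)
  expect_equal(find_overclustered_onset(build_cluster_tree(a)), 0.2)

  # dominant-parent tree: no onset
  b <- seq_assignments(c(2, 2, 4))
  expect_null(find_overclustered_onset(build_cluster_tree(b)))

  # a 0.95/0.05 newcomer has only one qualifying parent at low_inprop = 0.1
  c_ <- data.frame("0.1" = rep(c("A", "B"), c(100, 20)),
                   "0.2" = c(rep("a", 62), rep("n", 38),
                             rep("b", 18), rep("n", 2)),
                   check.names = FALSE)
  expect_null(find_overclustered_onset(build_cluster_tree(c_)))
})

test_that("selection takes the highest stable resolution below the onset", {
  # counts 2,2,3,3 then a multi-parent newcomer at 0.5
  a <- data.frame(
    "0.1" = rep(0:1, each = 60),
    "0.2" = rep(0:1, each = 60),
    "0.3" = rep(c(0, 2, 1), c(30, 30, 60)),
    "0.4" = rep(c(0, 2, 1), c(30, 30, 60)),
    "0.5" = c(rep(0, 20), rep(9, 10), rep(2, 30), rep(1, 50), rep(9, 10)),
    check.names = FALSE)
  rep_ <- select_resolution(build_cluster_tree(a))
  expect_equal(rep_$overclustered_onset, 0.5)
  expect_equal(rep_$selected_resolution, 0.4)
  expect_equal(rep_$n_clusters, 3L)

  # single resolution input selects itself
  one <- select_resolution(build_cluster_tree(
    data.frame("0.3" = rep(0:1, each = 5), check.names = FALSE)))
  expect_equal(one$selected_resolution, 0.3)

  # selection is invariant to relabeling clusters at any resolution
  b <- a
  b[["0.3"]] <- c(7, 5, 3)[b[["0.3"]] + 1]
  rep_b <- select_resolution(build_cluster_tree(b))
  expect_equal(rep_b$selected_resolution, rep_$selected_resolution)
})

test_that("an onset at the second resolution falls back to the first", {
  # a newcomer with two parents at the very first step: the degenerate
  # stable region at the lowest scanned resolution is still selectable (the
  # widen-the-grid error is a defensive branch that a valid tree cannot
  # trigger, since a one-to-one stable run can never cross an onset step)
  a <- data.frame("0.1" = rep(c("A", "B"), each = 60),
                  "0.2" = c(rep("a", 40), rep("n", 20),
                            rep("b", 40), rep("n", 20)),
                  check.names = FALSE)
  rep_ <- select_resolution(build_cluster_tree(a))
  expect_equal(rep_$overclustered_onset, 0.2)
  expect_equal(rep_$selected_resolution, 0.1)
})

test_that("planted-cluster scan selects a resolution recovering K clusters", {
  hits <- vapply(1:5, function(s) {
    sim <- small_sim(seed = s + 100, n_clusters = 4, cells = 70L,
                     n_genes = 300L)
    qc <- qc_filter(sim$counts)
    norm <- lognormalize(qc$counts)
    sc <- regress_covariate(norm)
    hv <- variable_genes(norm, 150)
    scan <- cluster_scan(sc$values[, match(hv, sc$gene_meta$gene)],
                         resolutions = c(0.01, 0.05, 0.1, 0.2, 0.3, 0.5,
                                         0.7, 0.8, 0.9, 1),
                         n_pcs = 20, seed = 0)
    rep_ <- select_resolution(build_cluster_tree(scan))
    rep_$n_clusters == 4
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
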