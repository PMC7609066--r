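test_that("rank-sum p agrees with enumeration for all small two-group inputs", {
  # no ties
  expect_equal(rank_sum_p(c(1, 2, 3), c(4, 5, 6)),
               oracle_rank_sum_p(c(1, 2, 3), c(4, 5, 6)))
  # property sweep with ties, both n <= 8
  set.seed(101)
  for (i in 1:40) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- sample(0:4, n1, replace = TRUE)
    y <- sample(0:4, n2, replace = TRUE)
    expect_equal(rank_sum_p(x, y), oracle_rank_sum_p(x, y),
                 tolerance = 1e-12,
                 label = sprintf("fixture %d (n1=%d n2=%d)", i, n1, n2))
  }
})

test_that("rank-sum normal path: identical groups give p = 1, matches wilcox.test", {
  x <- rep(2, 15); y <- rep(2, 15)
  expect_equal(rank_sum_p(x, y), 1)
  set.seed(5)
  a <- rnorm(30); b <- rnorm(25, 0.5)
  expect_equal(rank_sum_p(a, b),
               stats::wilcox.test(a, b, correct = TRUE, exact = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("marker logFC follows the pseudocounted de-logged mean ratio", {
  # in-cluster mean(e^x - 1) = 3, out 1 -> logFC = ln(4/2) = ln 2
  vals <- matrix(log1p(c(3, 3, 3, 1, 1, 1)), ncol = 1)
  norm <- ccmEC:::new_normalized_matrix(
    Matrix::Matrix(vals, sparse = TRUE),
    cell_meta = data.frame(cell_id = sprintf("c%d", 1:6)),
    gene_meta = data.frame(gene = "g1"), scale_factor = 1e4,
    n_umi = rep(1, 6))
  res <- rank_markers_one_vs_rest(norm, clusters = rep(c(1, 0), each = 3),
                                  cluster = 1)
  expect_equal(res$logFC, log(2))
  expect_equal(res$pct_in, 1)
  # identical distributions: logFC 0 and p = 1
  vals2 <- matrix(rep(log1p(2), 8), ncol = 1)
  norm2 <- ccmEC:::new_normalized_matrix(
    Matrix::Matrix(vals2, sparse = TRUE),
    cell_meta = data.frame(cell_id = sprintf("c%d", 1:8)),
    gene_meta = data.frame(gene = "g1"), scale_factor = 1e4,
    n_umi = rep(1, 8))
  res2 <- rank_markers_one_vs_rest(norm2, rep(0:1, each = 4), 0)
  expect_equal(res2$logFC, 0)
  expect_equal(res2$p, 1)
  # tiny cluster flagged untestable
  res3 <- rank_markers_one_vs_rest(norm2, c(0, 0, 1, 1, 1, 1, 1, 1), 0)
  expect_true(all(res3$untestable))
})

test_that("Tippett combination matches its closed form and properties", {
  expect_equal(combine_min_p(0.03), 0.03)
  expect_equal(combine_min_p(c(0.01, 0.5)), 1 - 0.99^2)
  expect_equal(combine_min_p(c(1, 1)), 1)
  expect_equal(combine_min_p(c(0.001, 0.9)), 1 - 0.999^2, tolerance = 1e-12)
  expect_error(combine_min_p(numeric(0)), "empty")
  expect_error(combine_min_p(c(0.5, 1.2)), "0, 1")
  # monotone non-decreasing in min p, bounded in [0, 1]
  ps <- seq(0, 1, by = 0.05)
  out <- vapply(ps, function(p) combine_min_p(c(p, 0.99)), numeric(1))
  expect_true(all(diff(out) >= 0))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("conserved markers recover planted markers with positive avg_logFC", {
  sim <- small_sim(seed = 21, n_clusters = 3, cells = 90L, n_genes = 300L)
  norm <- lognormalize(sim$counts)
  cl <- truth_clusters(sim, norm)
  mk <- conserved_markers(norm, cl)
  planted <- sim$truth$genes[!is.na(sim$truth$genes$marker_of), ]
  for (k in 0:2) {
    genes_k <- planted$gene[planted$marker_of == k]
    rows <- mk[mk$cluster == k & mk$gene %in% genes_k, ]
    expect_equal(nrow(rows), length(genes_k))
    expect_true(all(rows$avg_logFC > 0))
    expect_true(all(rows$p_combined < 0.05))
  }
  # single-genotype cluster is skipped with a warning
  cl2 <- cl
  gt <- norm$cell_meta$genotype
  cl2[cl == 0 & gt == "ko"] <- 1
  expect_warning(conserved_markers(norm, cl2), "only one genotype")
})

test_that("annotation applies the inclusive 50% key-gene rule", {
  mk <- data.frame(cluster = rep(c(0, 1), each = 10),
                   gene = rep(sprintf("g%02d", 1:10), 2),
                   avg_logFC = c(rep(1, 5), rep(-1, 5), rep(1, 10)),
                   p_combined = c(rep(0.001, 10), rep(0.001, 2),
                                  rep(0.5, 8)),
                   p_adj = 0.001)
  attr(mk, "all_genes") <- c(sprintf("g%02d", 1:10))
  panel <- data.frame(cell_type = "typeA", gene = sprintf("g%02d", 1:10))
  ann <- annotate_clusters(mk, panel)
  # cluster 0: exactly 5 of 10 keys pass -> annotated (boundary inclusive)
  expect_true(ann$annotated[ann$cluster == 0])
  expect_equal(ann$fraction[ann$cluster == 0], 0.5)
  # cluster 1: only 2 keys pass -> not annotated
  expect_false(ann$annotated[ann$cluster == 1])
  # absent key genes count as misses and are reported
  panel2 <- data.frame(cell_type = "typeB",
                       gene = c(sprintf("g%02d", 1:5), "NotAGene"))
  ann2 <- annotate_clusters(mk, panel2)
  expect_equal(attr(ann2, "warnings"), "NotAGene")
  expect_equal(ann2$n_key[1], 6L)
  # zero passing keys -> fraction 0
  panel3 <- data.frame(cell_type = "typeC", gene = sprintf("g%02d", 6:10))
  ann3 <- annotate_clusters(mk, panel3)
  expect_equal(ann3$fraction[ann3$cluster == 0], 0)
  # invariance to key order
  ann4 <- annotate_clusters(mk, panel[10:1, ])
  expect_equal(ann4$annotated, ann$annotated)
})

test_that("genotype DEGs recover planted ko effects with correct sign", {
  de <- list("1" = setNames(c(rep(log(4), 10), rep(-log(4), 10)),
                            sprintf("Gene%05d", 101:120)))
  cfg <- sim_config(n_clusters = 3, cells_per_cluster_wt = rep(250L, 3),
                    expansion_factor_ko = rep(1, 3), n_genes = 300,
                    de_genes_ko = de, seed = 33)
  sim <- simulate_cells(cfg)
  norm <- lognormalize(sim$counts)
  cl <- truth_clusters(sim, norm)
  res <- deg_ko_vs_wt(norm, cl)
  hits <- res$degs[res$degs$cluster == 1 & res$degs$significant, ]
  planted <- sprintf("Gene%05d", 101:120)
  expect_gte(sum(planted %in% hits$gene), 18)
  up <- hits[hits$gene %in% sprintf("Gene%05d", 101:110), ]
  dn <- hits[hits$gene %in% sprintf("Gene%05d", 111:120), ]
  expect_true(all(up$direction == "up"))
  expect_true(all(dn$direction == "down"))
  # no planted effects elsewhere: other clusters stay (nearly) clean
  other <- res$summary[res$summary$cluster != 1, ]
  expect_true(all(other$n_up + other$n_down <= 1))
})

test_that("uniqueness rules require passing in exactly one cluster", {
  mk <- data.frame(cluster = rep(c(0, 1), each = 3),
                   gene = c("a", "b", "c", "a", "d", "e"),
                   avg_logFC = c(1, 1, 0.1, 1, 1, 1),
                   p_combined = 0.001,
                   p_adj = c(0.001, 0.001, 0.001, 0.001, 0.001, 0.2))
  um <- unique_markers(mk)
  # "a" passes in both clusters -> unique in neither; "c" fails logFC;
  # "e" fails padj; unique: b (cluster 0), d (cluster 1)
  expect_equal(um$gene, c("b", "d"))
  expect_equal(um$cluster, c(0, 1))

  degs <- data.frame(cluster = rep(c(0, 1), each = 3),
                     gene = c("a", "b", "c", "a", "d", "e"),
                     logFC = c(1, -1, 0.1, 1, 1, 1),
                     padj = c(0.001, 0.001, 0.001, 0.001, 0.001, 0.2),
                     direction = c("up", "down", "up", "up", "up", "up"))
  ud <- unique_degs(degs)
  expect_equal(ud$gene, c("b", "d"))   # |logFC| rule keeps the down gene
})

test_that("planted unique vs shared markers separate exactly", {
  # plant 5 genes as markers of cluster 0 only and 5 shared across 0 and 1
  # via ko DE machinery is indirect; instead assemble marker tables from two
  # simulations' statistics -- here we test on the rule level with a
  # generated table derived from a real run
  sim <- small_sim(seed = 55, n_clusters = 3, cells = 90L, n_genes = 300L)
  norm <- lognormalize(sim$counts)
  cl <- truth_clusters(sim, norm)
  mk <- conserved_markers(norm, cl)
  um <- unique_markers(mk)
  planted <- sim$truth$genes[!is.na(sim$truth$genes$marker_of), ]
  # every planted marker is unique to its own cluster (folds are cluster
  # specific by construction)
  for (k in 0:2) {
    expect_true(all(planted$gene[planted$marker_of == k] %in%
                      um$gene[um$cluster == k]))
  }
})
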