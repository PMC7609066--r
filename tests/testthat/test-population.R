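test_that("expansion statistic matches the closed-form t interval", {
  counts <- data.frame(group = letters[1:4], wt = rep(10, 4),
                       ko = c(10, 10, 10, 50))
  res <- expansion_fold(counts)
  folds <- c(1, 1, 1, 5)
  m <- mean(folds); s <- sd(folds); n <- 4
  upper <- m + qt(0.975, n - 1) * s / sqrt(n)
  expect_equal(res$mean_fold, 2)
  expect_equal(res$sd_fold, 2)
  expect_equal(res$upper_limit, upper, tolerance = 1e-10)
  expect_identical(res$table$flagged, folds > upper)

  # equal counts everywhere: folds 1, SD 0, nothing flagged (strict >)
  eq <- expansion_fold(data.frame(group = 1:3, wt = c(5, 8, 9),
                                  ko = c(5, 8, 9)))
  expect_equal(eq$sd_fold, 0)
  expect_false(any(eq$table$flagged))
})

test_that("expansion handles exclusions, zero wt and scaling", {
  counts <- data.frame(group = c("a", "b", "c", "mixed"),
                       wt = c(10, 10, 0, 10), ko = c(10, 20, 5, 99))
  expect_warning(res <- expansion_fold(counts, exclude = "mixed"),
                 "zero wt")
  expect_equal(res$table$group, c("a", "b"))
  # scaling: multiplying ko by c multiplies folds by c; flags invariant
  c2 <- data.frame(group = letters[1:4], wt = rep(10, 4),
                   ko = c(10, 10, 10, 50))
  r1 <- expansion_fold(c2)
  c2$ko <- c2$ko * 3
  r2 <- expansion_fold(c2)
  expect_equal(r2$table$fold, r1$table$fold * 3)
  expect_identical(r2$table$flagged, r1$table$flagged)
  # relabeling groups does not change the statistics
  c3 <- data.frame(group = c("z", "y", "x", "w"), wt = rep(10, 4),
                   ko = c(10, 10, 10, 50))
  expect_equal(expansion_fold(c3)$upper_limit, r1$upper_limit)
  expect_error(expansion_fold(data.frame(group = "a", wt = 1, ko = 1)),
               ">= 2 groups")
})

pos_norm <- function(vals, genes = colnames(vals)) {
  ccmEC:::new_normalized_matrix(
    Matrix::Matrix(vals, sparse = TRUE),
    cell_meta = data.frame(cell_id = sprintf("c%03d", seq_len(nrow(vals)))),
    gene_meta = data.frame(gene = genes), scale_factor = 1e4,
    n_umi = rep(1, nrow(vals)))
}

test_that("positivity rules: >0, >Q1 with type-7 quartile, fixed threshold", {
  vals <- matrix(c(0, 0, 0, 0, 1, 2, 3, 4), ncol = 1,
                 dimnames = list(NULL, "Bst1"))
  norm <- pos_norm(vals)
  p0 <- positive_cells(norm, "Bst1", positivity_rule("gt_zero"))
  expect_equal(sum(p0), 4)
  # Q1 of {0,0,0,0,1,2,3,4} is 0 under type-7 -> positives are the nonzeros
  pq <- positive_cells(norm, "Bst1", positivity_rule("gt_q1"))
  expect_equal(attr(pq, "cutoff"),
               unname(quantile(vals[, 1], 0.25, type = 7)))
  expect_equal(which(as.logical(pq)), 5:8)
  # Q1 from a stated reference population, reused for all cells
  pr <- positive_cells(norm, "Bst1", positivity_rule("gt_q1"),
                       reference = 5:8)
  expect_equal(attr(pr, "cutoff"), unname(quantile(1:4, 0.25)))
  pt <- positive_cells(norm, "Bst1", positivity_rule("gt_threshold", 2.5))
  expect_equal(sum(pt), 2)
  # all-zero gene with gt_zero: all false
  norm0 <- pos_norm(matrix(0, 6, 1, dimnames = list(NULL, "Mki67")))
  expect_equal(sum(positive_cells(norm0, "Mki67")), 0)
  expect_error(positive_cells(norm, "Nope"), "Nope")
})

test_that("positivity fractions and CI folds flag a planted increase", {
  flagged <- vapply(1:20, function(s) {
    set.seed(s)
    n_groups <- 8; per <- 60
    groups <- rep(seq_len(n_groups) - 1, each = per * 2)
    genotypes <- rep(rep(c("wt", "ko"), each = per), n_groups)
    p <- ifelse(genotypes == "ko" & groups == 3, 0.6, 0.2)
    positives <- runif(length(p)) < p
    res <- suppressWarnings(
      positivity_fraction_fold(positives, groups, genotypes))
    res$expansion$table$flagged[res$expansion$table$group == 3]
  }, logical(1))
  expect_gte(mean(flagged), 0.9)
  # identical positivity: folds 1, no flags
  groups <- rep(0:3, each = 40)
  genotypes <- rep(rep(c("wt", "ko"), each = 20), 4)
  positives <- rep(rep(c(TRUE, FALSE), 10), 8)
  res <- positivity_fraction_fold(positives, groups, genotypes)
  expect_true(all(res$expansion$table$fold == 1))
  expect_false(any(res$expansion$table$flagged))
})

test_that("double-positive counts equal the set-intersection oracle", {
  vals <- cbind(Bst1 = c(1, 1, 0, 0, 2, 0), Mki67 = c(1, 0, 1, 0, 2, 0))
  norm <- pos_norm(vals)
  groups <- c("S0-S1", "S0-S1", "S0-S2", "S0-S2", "S0-S2", "S0-S1")
  genotypes <- c("wt", "ko", "wt", "ko", "ko", "wt")
  dp <- double_positive_counts(norm, "Bst1", "Mki67",
                               rule_a = positivity_rule("gt_zero"),
                               rule_b = positivity_rule("gt_zero"),
                               groups = groups, genotypes = genotypes)
  both <- vals[, 1] > 0 & vals[, 2] > 0
  for (i in seq_len(nrow(dp))) {
    expect_equal(dp$n_double_pos[i],
                 sum(both & groups == dp$group[i] &
                       genotypes == dp$genotype[i]))
  }
  # disjoint positive sets: zero everywhere
  vals2 <- cbind(A = c(1, 1, 0, 0), B = c(0, 0, 1, 1))
  dp2 <- double_positive_counts(pos_norm(vals2), "A", "B",
                                rule_a = positivity_rule("gt_zero"),
                                rule_b = positivity_rule("gt_zero"),
                                groups = rep("g", 4),
                                genotypes = c("wt", "ko", "wt", "ko"))
  expect_true(all(dp2$n_double_pos == 0))
  # double-positive count bounded by each single-positive count
  expect_true(all(dp$n_double_pos <=
                    tapply(vals[, 1] > 0, paste(groups, genotypes), sum)[
                      paste(dp$group, dp$genotype)]))
})

test_that("branch assignments load, validate and group like clusters", {
  tab <- data.frame(cell_id = c("c1", "c2", "c3"),
                    branch = c("S0-S1", "S0-S2", "S0-S1"))
  br <- load_branches(tab)
  expect_equal(unname(br[c("c1", "c3")]), c("S0-S1", "S0-S1"))
  expect_equal(as.integer(table(br)), c(2L, 1L))
  expect_error(load_branches(rbind(tab, tab[1, ])), "duplicate")
  expect_error(load_branches(tab, cell_ids = c("c1", "c2")), "unknown")
  # round trip through TSV
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(tab, path)
  expect_identical(load_branches(path, cell_ids = tab$cell_id), br)
})
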