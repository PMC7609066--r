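# Independent oracles used across the suite. These are deliberately written
# from the definitions (recursive enumeration, closed forms, step-up loops)
# rather than reusing the package's code paths.

# two-sided rank-sum p by recursive enumeration of all group-1 subsets
oracle_rank_sum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  mu <- n1 * (n + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  hits <- 0; total <- 0
  recurse <- function(start, left, acc) {
    if (left == 0) {
      total <<- total + 1
      if (abs(acc - mu) >= obs - 1e-9) hits <<- hits + 1
      return(invisible())
    }
    for (i in start:(n - left + 1)) recurse(i + 1, left - 1, acc + r[i])
  }
  recurse(1, n1, 0)
  hits / total
}

# hypergeometric upper tail P(X >= k) from binomial coefficients
oracle_hyper_upper <- function(k, K, N, n) {
  if (k <= 0) return(1)
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# two-sided Fisher exact p for a 2x2 table by point-probability enumeration
oracle_fisher_two_sided <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; K <- a + c; N <- a + b + c + d
  support <- max(0, m - (N - K)):min(m, K)
  pt <- choose(K, support) * choose(N - K, m - support) / choose(N, m)
  obs <- pt[support == a]
  sum(pt[pt <= obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up written out longhand
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[ord[i]] * n / i)
    q[ord[i]] <- val
    prev <- val
  }
  q
}

# spot truth table, rule by rule, as literal boolean expressions
oracle_spot_flags <- function(vals) {
  gt <- function(g, t) vals[, g] > t
  ec <- gt("Cldn5", 0.5) & gt("Cdh5", 0.5) & gt("Pecam1", 0.5)
  les <- ec & gt("Klf4", 0.5) & gt("Klf2", 0.5) & gt("Ly6a", 0.5) &
    gt("Thbd", 0.5)
  tip <- ec & gt("Apln", 0.5) & gt("Plaur", 0.5)
  mki <- gt("Mki67", 1)
  data.frame(ec = ec,
             proliferating_ec = ec & mki,
             lesion_ec = les,
             proliferating_lesion_ec = les & mki,
             tip_ec = tip,
             tip_lesion_ec = les & tip,
             proliferating_tip_ec = tip & mki,
             proliferating_tip_lesion_ec = les & tip & mki)
}

# wrap raw normalized spot values (spots x genes) for classify_spots
make_norm_spots <- function(vals) {
  ccmEC:::new_normalized_matrix(
    Matrix::Matrix(vals, sparse = TRUE),
    cell_meta = data.frame(spot_id = sprintf("s%03d", seq_len(nrow(vals))),
                           x = seq_len(nrow(vals)), y = 0,
                           sample = "ko1", genotype = "ko",
                           stringsAsFactors = FALSE),
    gene_meta = data.frame(gene = colnames(vals), stringsAsFactors = FALSE),
    scale_factor = 1e4, n_umi = rowSums(vals), kind = "spots")
}

# classify_spots-shaped flags realising a given 2x2 proliferation table
fisher_flags <- function(a_event, a_total, b_event, b_total) {
  # class-a spots are EC only; class-b are lesion EC
  n <- a_total + b_total
  data.frame(
    spot_id = sprintf("s%d", seq_len(n)),
    ec = TRUE,
    lesion_ec = rep(c(FALSE, TRUE), c(a_total, b_total)),
    proliferating_ec = rep(c(TRUE, FALSE, FALSE),
                           c(a_event, a_total - a_event, b_total)),
    proliferating_lesion_ec = rep(c(FALSE, TRUE, FALSE),
                                  c(a_total, b_event, b_total - b_event)))
}

# small simulation shared by several files
small_sim <- function(seed = 42, n_clusters = 4, cells = 100L,
                      n_genes = 400L, ...) {
  cfg <- sim_config(n_clusters = n_clusters,
                    cells_per_cluster_wt = rep(cells, n_clusters),
                    expansion_factor_ko = rep(1, n_clusters),
                    n_genes = n_genes, seed = seed, ...)
  simulate_cells(cfg)
}

truth_clusters <- function(sim, norm) {
  sim$truth$cells$cluster[match(norm$cell_meta$cell_id,
                                sim$truth$cells$cell_id)]
}
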