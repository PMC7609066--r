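## Synthetic-data generator. Emulates the statistical structure the downstream
## stages assume: negative-binomial counts with cluster-specific marker genes,
## two genotypes with per-cluster knockout expansion (cell counts set exactly,
## not sampled), Beta-distributed mitochondrial count shares, zero-inflation
## masks that hit configured marker-positivity targets, and spatial spots built
## as mixtures of cluster mean profiles with lesion / proliferation / tip
## structure. Every draw funnels through one seed; ground truth is returned
## next to the data.

MT_GENES <- c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Atp8", "mt-Atp6",
              "mt-Co3", "mt-Nd3", "mt-Nd4l", "mt-Nd4", "mt-Nd5", "mt-Nd6",
              "mt-Cytb")
EC_GENES <- c("Cldn5", "Cdh5", "Pecam1")
LESION_GENES <- c("Klf4", "Klf2", "Ly6a", "Thbd")
TIP_GENES <- c("Apln", "Plaur", "Mmrn2")
MITOTIC_GENES <- c("Mki67", "Plk1", "Mxd3", "Birc5", "Ube2c")
PROGENITOR_GENES <- c("Bst1", "Peg3", "Procr", "Cd200")

default_expansions <- function(n_clusters) {
  x <- rep(1, n_clusters)
  # mirror the strongest knockout expansions of the venous (C9) and
  # tip/capillary (C12) populations; labels are 0-based, so index i is C(i-1)
  if (n_clusters >= 10) x[10] <- 4.8
  if (n_clusters >= 13) x[13] <- 4.0
  x
}

#' Configuration for the synthetic single-cell world
#'
#' Defaults describe a desk-scale version of the system under study: 13
#' endothelial clusters, two genotypes (`wt`, `ko`), knockout expansion of the
#' venous cluster C9 (4.8-fold) and of C12 (4.0-fold), negative-binomial
#' counts, 13 mitochondrial genes carrying a ~2% count share, and fold-8
#' cluster markers.
#'
#' @param n_clusters number of planted clusters (labels `0 .. n_clusters-1`).
#' @param cells_per_cluster_wt integer vector of wild-type cells per cluster.
#' @param expansion_factor_ko positive reals; knockout cell count per cluster
#'   is `round(wt * factor)` (set exactly, not sampled).
#' @param n_genes total genes, including named panel genes and mito genes.
#' @param baseline_mean mean NB count per gene per cell before per-gene
#'   variation (gene means are `baseline_mean * Gamma(2, 2)` draws).
#' @param dispersion NB size (inverse-dispersion) parameter.
#' @param markers_per_cluster planted marker genes per cluster.
#' @param marker_fold mean multiplier of a cluster's markers in that cluster;
#'   must be > 1 (exactly 1 is allowed to express a null world).
#' @param de_genes_ko named list: cluster label (as character) -> named numeric
#'   vector of natural-log fold effects applied to knockout cells' means.
#' @param mito_gene_count number of mitochondrial genes.
#' @param mito_fraction_mean,mito_fraction_sd mean and SD of the Beta
#'   distributed per-cell mitochondrial count share.
#' @param positivity_profiles named list: gene -> list(wt =, ko =) of
#'   per-cluster target positive (count > 0) fractions in `[0, 1]`, realised
#'   by a Bernoulli zero-inflation mask over a high-mean NB draw.
#' @param ec_gene_mean NB mean of the pan-endothelial identity genes
#'   (Cldn5, Cdh5, Pecam1) in every cluster.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return validated object of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 13L,
                       cells_per_cluster_wt = rep(300L, n_clusters),
                       expansion_factor_ko = default_expansions(n_clusters),
                       n_genes = 2000L,
                       baseline_mean = 0.5,
                       dispersion = 2,
                       markers_per_cluster = 10L,
                       marker_fold = 8,
                       de_genes_ko = list(),
                       mito_gene_count = 13L,
                       mito_fraction_mean = 0.02,
                       mito_fraction_sd = 0.01,
                       positivity_profiles = list(),
                       ec_gene_mean = 5,
                       seed = 1L) {
  cfg <- list(n_clusters = as.integer(n_clusters),
              cells_per_cluster_wt = as.integer(cells_per_cluster_wt),
              expansion_factor_ko = as.numeric(expansion_factor_ko),
              n_genes = as.integer(n_genes),
              baseline_mean = baseline_mean,
              dispersion = dispersion,
              markers_per_cluster = as.integer(markers_per_cluster),
              marker_fold = marker_fold,
              de_genes_ko = de_genes_ko,
              mito_gene_count = as.integer(mito_gene_count),
              mito_fraction_mean = mito_fraction_mean,
              mito_fraction_sd = mito_fraction_sd,
              positivity_profiles = positivity_profiles,
              ec_gene_mean = ec_gene_mean,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_clusters) || cfg$n_clusters < 1)
    abort_field("n_clusters", "must be a positive integer")
  if (length(cfg$cells_per_cluster_wt) != cfg$n_clusters)
    abort_field("cells_per_cluster_wt",
                sprintf("length %d != n_clusters %d",
                        length(cfg$cells_per_cluster_wt), cfg$n_clusters))
  if (any(cfg$cells_per_cluster_wt < 0))
    abort_field("cells_per_cluster_wt", "cell counts must be >= 0")
  if (length(cfg$expansion_factor_ko) != cfg$n_clusters)
    abort_field("expansion_factor_ko", "length must equal n_clusters")
  if (any(cfg$expansion_factor_ko <= 0))
    abort_field("expansion_factor_ko", "expansion factors must be > 0")
  if (!is_count(cfg$n_genes) || cfg$n_genes < 1)
    abort_field("n_genes", "must be a positive integer")
  if (!is.numeric(cfg$baseline_mean) || cfg$baseline_mean <= 0)
    abort_field("baseline_mean", "must be > 0")
  if (!is.numeric(cfg$dispersion) || cfg$dispersion <= 0)
    abort_field("dispersion", "must be > 0")
  if (cfg$markers_per_cluster < 0)
    abort_field("markers_per_cluster", "must be >= 0")
  if (!is.numeric(cfg$marker_fold) || cfg$marker_fold < 1)
    abort_field("marker_fold", "must be >= 1")
  if (cfg$mito_gene_count < 0 || cfg$mito_gene_count > length(MT_GENES))
    abort_field("mito_gene_count",
                sprintf("must be in 0..%d", length(MT_GENES)))
  if (cfg$mito_fraction_mean < 0 || cfg$mito_fraction_mean > 1)
    abort_field("mito_fraction_mean", "must be in [0, 1]")
  if (cfg$mito_fraction_sd < 0 || cfg$mito_fraction_sd > 1)
    abort_field("mito_fraction_sd", "must be in [0, 1]")
  for (g in names(cfg$positivity_profiles)) {
    prof <- cfg$positivity_profiles[[g]]
    for (gt in c("wt", "ko")) {
      if (is.null(prof[[gt]]))
        abort_field("positivity_profiles",
                    sprintf("gene '%s' lacks '%s' targets", g, gt))
      if (length(prof[[gt]]) != cfg$n_clusters)
        abort_field("positivity_profiles",
                    sprintf("gene '%s' %s targets: length != n_clusters", g, gt))
      if (any(prof[[gt]] < 0 | prof[[gt]] > 1))
        abort_field("positivity_profiles",
                    sprintf("gene '%s': fractions must be in [0, 1]", g))
    }
  }
  special <- length(EC_GENES) + length(LESION_GENES) + length(TIP_GENES) +
    length(MITOTIC_GENES) + length(PROGENITOR_GENES)
  need <- cfg$mito_gene_count + special +
    cfg$n_clusters * cfg$markers_per_cluster
  if (cfg$n_genes < need)
    abort_field("n_genes",
                sprintf("need >= %d genes for mito + panel + markers", need))
  if (!is_count(abs(cfg$seed))) abort_field("seed", "must be an integer")
  invisible(cfg)
}

## NB mean used for genes whose positivity is mask-controlled; high enough
## that P(count > 0 | kept) is close to 1, so the mask sets the target.
POS_GENE_MEAN <- 10

sim_gene_table <- function(cfg) {
  special <- c(EC_GENES, LESION_GENES, TIP_GENES, MITOTIC_GENES,
               PROGENITOR_GENES)
  mito <- MT_GENES[seq_len(cfg$mito_gene_count)]
  n_fill <- cfg$n_genes - length(mito) - length(special)
  fill <- sprintf("Gene%05d", seq_len(n_fill))
  data.frame(gene = c(mito, special, fill),
             mito = c(rep(TRUE, length(mito)),
                      rep(FALSE, length(special) + n_fill)),
             stringsAsFactors = FALSE)
}

#' Simulate a cell-by-gene count matrix with ground truth
#'
#' Draws negative-binomial counts per cluster and genotype. Knockout cell
#' counts per cluster are `round(wt * expansion_factor_ko)` exactly, so the
#' truth behind the expansion statistic is unambiguous. Mitochondrial genes
#' receive a Beta-distributed share of each cell's expected depth; genes with
#' positivity profiles are zero-inflated to the configured targets.
#'
#' @param config a [sim_config()].
#' @return list with elements `counts` ([count_matrix()]) and `truth` (list
#'   with `cells`, `genes`, `de` data frames and the `config`).
#' @export
simulate_cells <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  genes <- sim_gene_table(config)
  G <- config$n_genes

  base_mean <- config$baseline_mean * stats::rgamma(G, shape = 2, rate = 2)
  base_mean[match(EC_GENES, genes$gene)] <- config$ec_gene_mean
  pos_genes <- names(config$positivity_profiles)
  if (length(pos_genes)) {
    idx <- match(pos_genes, genes$gene)
    if (anyNA(idx))
      abort_field("positivity_profiles",
                  sprintf("gene(s) not in the simulated panel: %s",
                          paste(pos_genes[is.na(idx)], collapse = ", ")))
    base_mean[idx] <- POS_GENE_MEAN
  }

  # markers are drawn from the unnamed filler pool so panel genes stay free
  fill_idx <- which(!genes$mito &
                      !genes$gene %in% c(EC_GENES, LESION_GENES, TIP_GENES,
                                         MITOTIC_GENES, PROGENITOR_GENES,
                                         pos_genes))
  marker_of <- rep(NA_integer_, G)
  if (config$markers_per_cluster > 0) {
    picked <- sample(fill_idx, config$n_clusters * config$markers_per_cluster)
    marker_of[picked] <- rep(0:(config$n_clusters - 1L),
                             each = config$markers_per_cluster)
    # markers model canonical, detectably expressed genes: floor their
    # baseline at the configured mean so a fold change is observable
    base_mean[picked] <- pmax(base_mean[picked], config$baseline_mean)
  }

  mito_idx <- which(genes$mito)
  n_mito <- length(mito_idx)
  # Beta parameters from mean/sd by moment matching
  m <- config$mito_fraction_mean
  s <- config$mito_fraction_sd
  beta_draw <- function(n) {
    if (n_mito == 0 || m == 0) return(rep(0, n))
    if (s == 0) return(rep(m, n))
    v <- min(s^2, m * (1 - m) * 0.999)
    nu <- m * (1 - m) / v - 1
    stats::rbeta(n, m * nu, (1 - m) * nu)
  }

  n_wt <- config$cells_per_cluster_wt
  n_ko <- as.integer(round(n_wt * config$expansion_factor_ko))

  de <- config$de_genes_ko
  de_rows <- list()

  blocks <- list()
  meta <- list()
  for (k in 0:(config$n_clusters - 1L)) {
    mu_k <- base_mean
    mk <- which(marker_of == k)
    mu_k[mk] <- mu_k[mk] * config$marker_fold
    for (gt in c("wt", "ko")) {
      n_b <- if (gt == "wt") n_wt[k + 1L] else n_ko[k + 1L]
      if (n_b == 0) next
      mu <- mu_k
      if (gt == "ko" && !is.null(de[[as.character(k)]])) {
        eff <- de[[as.character(k)]]
        gi <- match(names(eff), genes$gene)
        if (anyNA(gi))
          abort_field("de_genes_ko",
                      sprintf("unknown gene(s): %s",
                              paste(names(eff)[is.na(gi)], collapse = ", ")))
        mu[gi] <- mu[gi] * exp(eff)
      }
      M <- matrix(rep(mu, each = n_b), nrow = n_b)
      if (n_mito > 0 && m > 0) {
        f <- beta_draw(n_b)
        depth <- sum(mu[-mito_idx])
        M[, mito_idx] <- (f / (1 - f)) * depth / n_mito
      }
      cnt <- matrix(stats::rnbinom(n_b * G, size = config$dispersion, mu = M),
                    nrow = n_b)
      for (g in pos_genes) {
        q <- config$positivity_profiles[[g]][[gt]][k + 1L]
        gi <- match(g, genes$gene)
        p0 <- 1 - stats::dnbinom(0, size = config$dispersion,
                                 mu = POS_GENE_MEAN)
        keep <- min(1, q / p0)
        cnt[, gi] <- cnt[, gi] * stats::rbinom(n_b, 1L, keep)
      }
      blocks[[length(blocks) + 1L]] <- cnt
      meta[[length(meta) + 1L]] <-
        data.frame(cluster = k, genotype = gt,
                   sample = paste0(gt, rep_len(1:2, n_b)),
                   stringsAsFactors = FALSE)
    }
  }

  counts <- do.call(rbind, blocks)
  cells <- do.call(rbind, meta)
  n_cells <- nrow(cells)
  perm <- sample.int(n_cells)
  counts <- counts[perm, , drop = FALSE]
  cells <- cells[perm, , drop = FALSE]
  cells$cell_id <- sprintf("cell%06d", seq_len(n_cells))
  rownames(cells) <- NULL

  for (k in names(de))
    de_rows[[k]] <- data.frame(cluster = as.integer(k),
                               gene = names(de[[k]]),
                               lfc = unname(de[[k]]),
                               stringsAsFactors = FALSE)
  de_tab <- if (length(de_rows)) do.call(rbind, de_rows) else
    data.frame(cluster = integer(), gene = character(), lfc = numeric())
  rownames(de_tab) <- NULL

  cm <- count_matrix(Matrix::drop0(Matrix::Matrix(counts, sparse = TRUE)),
                     cell_meta = cells[, c("cell_id", "sample", "genotype")],
                     gene_meta = genes)
  truth <- list(cells = cells[, c("cell_id", "cluster", "genotype", "sample")],
                genes = data.frame(gene = genes$gene, mito = genes$mito,
                                   marker_of = marker_of,
                                   base_mean = base_mean,
                                   stringsAsFactors = FALSE),
                de = de_tab,
                config = config)
  list(counts = cm, truth = truth)
}

#' Key-gene panel implied by the simulation ground truth
#'
#' Builds the cell-type -> key-gene mapping (`type<k>` per planted cluster)
#' that [annotate_clusters()] consumes, from the markers the generator planted.
#'
#' @param truth the `truth` element returned by [simulate_cells()].
#' @return data frame with columns `cell_type`, `gene`.
#' @export
truth_key_panel <- function(truth) {
  g <- truth$genes
  g <- g[!is.na(g$marker_of), ]
  data.frame(cell_type = paste0("type", g$marker_of), gene = g$gene,
             stringsAsFactors = FALSE)
}

#' Simulate spatial spots as mixtures of cluster profiles
#'
#' Each spot's expected expression is a mixture of the simulated cluster mean
#' profiles plus a non-endothelial background profile, scaled to a per-spot
#' sequencing depth; counts are Poisson. Lesion spots have elevated lesion
#' marker means (Klf4, Klf2, Ly6a, Thbd), proliferating spots elevated Mki67,
#' tip spots elevated Apln/Plaur/Mmrn2; outside those spots these genes sit at
#' a near-zero floor so that downstream threshold rules have a clean truth.
#' Spots are laid on a square grid and split over two knockout samples.
#'
#' @param config a [sim_config()]; supplies gene panel and cluster profiles.
#' @param n_spots number of spots.
#' @param mixing optional `n_spots x (n_clusters + 1)` matrix of per-spot
#'   mixing proportions over clusters plus background (last column); rows must
#'   sum to 1 within 1e-9. When `NULL`, mixtures are generated from the class
#'   fractions below.
#' @param ec_frac fraction of spots containing endothelium.
#' @param lesion_frac,prolif_frac,tip_frac fractions of EC spots with lesion /
#'   proliferation / tip structure (drawn independently within EC spots).
#' @param depth expected total counts per spot.
#' @param struct_mean NB mean given to structure genes in flagged spots.
#' @param floor_mean mean floor of structure genes elsewhere.
#' @param seed integer; defaults to `config$seed + 1`.
#' @return list with `spots` ([spot_matrix()]) and `truth` data frame
#'   (`spot_id`, `ec`, `ec_mix`, `lesion`, `prolif`, `tip`).
#' @export
simulate_spots <- function(config, n_spots = 500L, mixing = NULL,
                           ec_frac = 0.6, lesion_frac = 0.3,
                           prolif_frac = 0.25, tip_frac = 0.2,
                           depth = 5000, struct_mean = 5,
                           floor_mean = 0.002, seed = config$seed + 1L) {
  validate_sim_config(config)
  set.seed(seed)
  genes <- sim_gene_table(config)
  G <- config$n_genes
  K <- config$n_clusters

  base_mean <- config$baseline_mean * stats::rgamma(G, shape = 2, rate = 2)
  ec_idx <- match(EC_GENES, genes$gene)
  struct_genes <- c(LESION_GENES, TIP_GENES, "Mki67")
  struct_idx <- match(struct_genes, genes$gene)

  profiles <- matrix(rep(base_mean, each = K), nrow = K)
  profiles[, ec_idx] <- config$ec_gene_mean
  profiles[, struct_idx] <- floor_mean
  background <- base_mean
  background[c(ec_idx, struct_idx,
               match(PROGENITOR_GENES, genes$gene))] <- floor_mean
  profiles <- rbind(profiles, background)     # row K+1 = background

  if (is.null(mixing)) {
    ec <- stats::runif(n_spots) < ec_frac
    mixing <- matrix(0, n_spots, K + 1L)
    for (i in seq_len(n_spots)) {
      w <- stats::rgamma(K, 1, 1)
      w <- w / sum(w)
      if (ec[i]) {
        mixing[i, ] <- c(0.7 * w, 0.3)
      } else {
        mixing[i, ] <- c(0.005 * w, 0.995)
      }
    }
  } else {
    mixing <- as.matrix(mixing)
    if (nrow(mixing) != n_spots || ncol(mixing) != K + 1L)
      stopf("mixing must be %d x %d (clusters + background)", n_spots, K + 1L)
    if (any(abs(rowSums(mixing) - 1) > 1e-9))
      stopf("mixing rows must sum to 1 within 1e-9; worst deviation %.3g",
            max(abs(rowSums(mixing) - 1)))
    ec <- mixing[, K + 1L] < 0.5
  }

  lesion <- ec & stats::runif(n_spots) < lesion_frac
  prolif <- ec & stats::runif(n_spots) < prolif_frac
  tip <- ec & stats::runif(n_spots) < tip_frac

  M <- mixing %*% profiles
  les_idx <- match(LESION_GENES, genes$gene)
  tip_idx <- match(TIP_GENES, genes$gene)
  mki_idx <- match("Mki67", genes$gene)
  M[lesion, les_idx] <- struct_mean
  M[tip, tip_idx] <- struct_mean
  M[prolif, mki_idx] <- struct_mean

  scale <- depth / rowSums(M)
  lambda <- M * scale
  cnt <- matrix(stats::rpois(length(lambda), lambda), nrow = n_spots)

  side <- ceiling(sqrt(n_spots))
  spot_meta <- data.frame(
    spot_id = sprintf("spot%05d", seq_len(n_spots)),
    x = (seq_len(n_spots) - 1L) %% side,
    y = (seq_len(n_spots) - 1L) %/% side,
    sample = paste0("ko", rep_len(1:2, n_spots)),
    genotype = "ko",
    stringsAsFactors = FALSE)

  sm <- spot_matrix(Matrix::drop0(Matrix::Matrix(cnt, sparse = TRUE)),
                    spot_meta, genes["gene"])
  truth <- data.frame(spot_id = spot_meta$spot_id,
                      ec = ec, ec_mix = 1 - mixing[, K + 1L],
                      lesion = lesion, prolif = prolif, tip = tip,
                      stringsAsFactors = FALSE)
  list(spots = sm, truth = truth)
}

#' Write a count matrix in Cell-Ranger-style Matrix Market layout
#'
#' Writes `matrix.mtx` (genes x cells, as Cell Ranger does), `barcodes.tsv`,
#' `features.tsv` and `cell_meta.tsv` into `dir`.
#'
#' @param counts a [count_matrix()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::t(counts$values), file.path(dir, "matrix.mtx"))
  writeLines(counts$cell_meta$cell_id, file.path(dir, "barcodes.tsv"))
  writeLines(counts$gene_meta$gene, file.path(dir, "features.tsv"))
  write_tsv(counts$cell_meta, file.path(dir, "cell_meta.tsv"))
  invisible(dir)
}

#' Write a spot matrix as a single TSV
#'
#' Columns: `spot_id`, `x`, `y`, `sample`, `genotype`, then one column per
#' gene with raw counts.
#'
#' @param spots a [spot_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spots_tsv <- function(spots, path) {
  df <- cbind(spots$spot_meta,
              as.data.frame(as.matrix(spots$values), check.names = FALSE))
  write_tsv(df, path)
}

#' Read a spot TSV written by [write_spots_tsv()]
#'
#' @param path file path.
#' @return a [spot_matrix()].
#' @export
read_spots_tsv <- function(path) {
  df <- read_tsv(path)
  meta_cols <- c("spot_id", "x", "y", "sample", "genotype")
  missing <- setdiff(meta_cols, names(df))
  if (length(missing))
    stopf("spot table lacks column(s): %s", paste(missing, collapse = ", "))
  vals <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  spot_matrix(vals, df[meta_cols],
              data.frame(gene = colnames(vals), stringsAsFactors = FALSE))
}
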