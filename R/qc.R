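## Quality control, normalization, covariate regression and variable-gene
## selection. The QC rule set follows the study design: detected-gene bounds
## of mean +/- k * SD computed within each genotype after merging its samples,
## plus a hard cap on the per-cell mitochondrial count fraction. Both rules
## are evaluated on the input matrix in a single pass (the order would change
## the removed set; see the methods vignette).

#' Filter cells on detected genes and mitochondrial fraction
#'
#' A cell is removed iff its number of detected genes (genes with count > 0)
#' lies strictly outside mean +/- `sd_k` * SD of detected genes within its
#' genotype group, or its mitochondrial count fraction is strictly greater
#' than `mito_max`. SD is the sample standard deviation. Cells exactly on a
#' bound are retained.
#'
#' @param counts a [count_matrix()] with mito flags in `gene_meta`.
#' @param sd_k number of SDs; default 2.
#' @param mito_max maximum tolerated mitochondrial fraction; default 0.05.
#' @return list with `counts` (the retained cells) and `report`: a list with
#'   `per_cell` (cell_id, genotype, detected, mito_frac, pass, reasons),
#'   `group_stats` (genotype, mean, sd, lower, upper), and `removed`
#'   (rule-wise and total removal counts; a cell can fail both rules).
#' @export
qc_filter <- function(counts, sd_k = 2, mito_max = 0.05) {
  v <- counts$values
  detected <- Matrix::rowSums(v > 0)
  total <- Matrix::rowSums(v)
  mito_counts <- if (any(counts$gene_meta$mito))
    Matrix::rowSums(v[, counts$gene_meta$mito, drop = FALSE]) else
      rep(0, nrow(v))
  mito_frac <- ifelse(total > 0, mito_counts / total, 0)
  gt <- counts$cell_meta$genotype

  gstats <- do.call(rbind, lapply(split(detected, gt), function(d) {
    if (length(d) < 2)
      stopf("genotype group with %d cell(s): SD undefined", length(d))
    c(mean = mean(d), sd = stats::sd(d))
  }))
  group_stats <- data.frame(genotype = rownames(gstats),
                            mean = gstats[, "mean"], sd = gstats[, "sd"],
                            lower = gstats[, "mean"] - sd_k * gstats[, "sd"],
                            upper = gstats[, "mean"] + sd_k * gstats[, "sd"],
                            row.names = NULL, stringsAsFactors = FALSE)
  gi <- match(gt, group_stats$genotype)
  fail_low <- detected < group_stats$lower[gi]
  fail_high <- detected > group_stats$upper[gi]
  fail_mito <- mito_frac > mito_max
  pass <- !(fail_low | fail_high | fail_mito)

  reasons <- character(length(pass))
  reasons[fail_low] <- "detected_low"
  reasons[fail_high] <- "detected_high"
  reasons[fail_mito] <- ifelse(reasons[fail_mito] == "", "mito",
                               paste(reasons[fail_mito], "mito", sep = ";"))
  per_cell <- data.frame(cell_id = counts$cell_meta$cell_id,
                         genotype = gt, detected = as.integer(detected),
                         mito_frac = mito_frac, pass = pass,
                         reasons = reasons, stringsAsFactors = FALSE)
  removed <- c(detected_low = sum(fail_low), detected_high = sum(fail_high),
               mito = sum(fail_mito), total = sum(!pass))
  kept <- count_matrix(v[pass, , drop = FALSE],
                       counts$cell_meta[pass, , drop = FALSE],
                       counts$gene_meta)
  list(counts = kept,
       report = list(per_cell = per_cell, group_stats = group_stats,
                     removed = removed, retained = sum(pass)))
}

#' Log-normalize counts to a fixed scale factor
#'
#' `value = ln(1 + count * scale / cell_total)`; default scale 10,000. Works
#' for cells ([count_matrix()]) and spots ([spot_matrix()]); all downstream
#' thresholds, tests and fold changes operate on these values.
#'
#' @param x a [count_matrix()] or [spot_matrix()].
#' @param scale scale factor, default 1e4.
#' @return a `NormalizedMatrix` (keeps the raw counts for variance
#'   stabilisation and the per-cell totals as `n_umi`).
#' @export
lognormalize <- function(x, scale = 1e4) {
  spots <- inherits(x, "SpotMatrix")
  if (!spots && !inherits(x, "CountMatrix"))
    stopf("x must be a CountMatrix or SpotMatrix")
  v <- x$values
  total <- Matrix::rowSums(v)
  if (any(total == 0)) {
    ids <- if (spots) x$spot_meta$spot_id else x$cell_meta$cell_id
    stopf("zero-total %s: %s", if (spots) "spot(s)" else "cell(s)",
          paste(utils::head(ids[total == 0], 5), collapse = ", "))
  }
  norm <- v
  norm@x <- log1p(norm@x * (scale / total)[norm@i + 1L])
  new_normalized_matrix(norm,
                        cell_meta = if (spots) x$spot_meta else x$cell_meta,
                        gene_meta = x$gene_meta,
                        scale_factor = scale, n_umi = as.numeric(total),
                        counts = v, kind = if (spots) "spots" else "cells")
}

#' Regress a per-cell covariate out of normalized expression and z-scale
#'
#' Per gene: residuals of a simple linear fit of normalized expression on the
#' covariate (default total molecules per cell, nUMI), then centered and unit
#' scaled. Genes with zero residual variance map to all-zero columns; a
#' constant covariate reduces to plain per-gene z-scoring.
#'
#' @param norm a `NormalizedMatrix` from [lognormalize()].
#' @param covariate `"nUMI"` (default) or a numeric vector, one value per cell.
#' @return list of class `ScaledMatrix`: `values` (dense cells x genes),
#'   `cell_meta`, `gene_meta`, `covariate` name.
#' @export
regress_covariate <- function(norm, covariate = "nUMI") {
  x <- if (is.character(covariate) && identical(covariate, "nUMI"))
    norm$n_umi else as.numeric(covariate)
  if (length(x) != nrow(norm$values))
    stopf("covariate length %d != %d cells", length(x), nrow(norm$values))
  if (any(!is.finite(x))) stopf("covariate must be finite for all cells")
  Y <- as.matrix(norm$values)
  xc <- x - mean(x)
  vx <- sum(xc^2)
  if (vx > 0) {
    beta <- as.numeric(crossprod(Y, xc)) / vx     # per-gene slope
    R <- sweep(Y, 2, colMeans(Y)) - outer(xc, beta)
  } else {
    R <- sweep(Y, 2, colMeans(Y))
  }
  sds <- sqrt(colSums(R^2) / (nrow(R) - 1))
  keep <- sds > 0
  R[, keep] <- sweep(R[, keep, drop = FALSE], 2, sds[keep], "/")
  R[, !keep] <- 0
  structure(list(values = R, cell_meta = norm$cell_meta,
                 gene_meta = norm$gene_meta,
                 covariate = if (is.character(covariate)) covariate else
                   "custom"),
            class = "ScaledMatrix")
}

#' Select highly variable genes by standardized variance
#'
#' Variance-stabilizing-transform family: a degree-2 polynomial is fit to
#' log10(variance) versus log10(mean) of the raw counts; counts are
#' standardized by the fitted (expected) SD, clipped at sqrt(n_cells), and
#' genes are ranked by the variance of the clipped standardized counts.
#' Ties are broken by gene symbol for determinism.
#'
#' @param norm a `NormalizedMatrix` carrying raw counts.
#' @param n_top number of genes to return (default 2000).
#' @return character vector of `n_top` gene symbols, most variable first.
#' @export
variable_genes <- function(norm, n_top = 2000) {
  counts <- norm$counts
  if (is.null(counts)) stopf("normalized matrix does not carry raw counts")
  G <- ncol(counts)
  if (n_top > G) stopf("n_top (%d) exceeds gene count (%d)", n_top, G)
  n <- nrow(counts)
  mu <- Matrix::colMeans(counts)
  ex2 <- Matrix::colMeans(counts^2)
  v <- (ex2 - mu^2) * n / (n - 1)

  std_var <- numeric(G)
  fit_ok <- mu > 0 & v > 0
  if (sum(fit_ok) >= 3) {
    fit <- stats::lm(log10(v[fit_ok]) ~ stats::poly(log10(mu[fit_ok]), 2))
    esd <- sqrt(10^stats::predict(fit))
    clip <- sqrt(n)
    cc <- methods::as(counts[, fit_ok, drop = FALSE], "CsparseMatrix")
    mu_f <- mu[fit_ok]
    ptr <- cc@p
    for (j in seq_len(ncol(cc))) {
      xs <- if (ptr[j + 1L] > ptr[j])
        cc@x[(ptr[j] + 1L):ptr[j + 1L]] else numeric(0)
      z0 <- pmax(pmin((0 - mu_f[j]) / esd[j], clip), -clip)
      zx <- pmax(pmin((xs - mu_f[j]) / esd[j], clip), -clip)
      n0 <- n - length(xs)
      zm <- (n0 * z0 + sum(zx)) / n
      std_var[which(fit_ok)[j]] <-
        (n0 * (z0 - zm)^2 + sum((zx - zm)^2)) / (n - 1)
    }
  }
  ord <- order(-std_var, norm$gene_meta$gene)
  norm$gene_meta$gene[ord][seq_len(n_top)]
}
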