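## Cluster/branch abundance and positivity statistics: the knockout-vs-wild
## type fold change per group with a t-based 95% confidence-interval upper
## limit computed over the group family, and the >0 / >Q1 / >threshold
## positivity rules.

#' Fold-change expansion statistic with CI flagging
#'
#' Per group (cluster or trajectory branch): fold = ko count / wt count. The
#' flagging limit is `mean(folds) + t_{(1+level)/2, n-1} * SD(folds)/sqrt(n)`
#' over the n included groups (sample SD); a group is flagged when its fold is
#' strictly above the limit. Groups with zero wild-type cells are excluded
#' with a warning; groups can also be excluded from the family explicitly
#' (e.g. mixed, non-endothelial clusters).
#'
#' @param counts data frame with columns `group`, `wt`, `ko` (cell counts), or
#'   a 2-column matrix with groups as row names and columns `wt`, `ko`.
#' @param level confidence level (default 0.95).
#' @param exclude optional vector of group labels left out of the family.
#' @return list of class `expansion_table`: `table` (group, wt, ko, fold,
#'   flagged), `mean_fold`, `sd_fold`, `upper_limit`, `level`, `n`.
#' @export
expansion_fold <- function(counts, level = 0.95, exclude = NULL) {
  if (is.matrix(counts))
    counts <- data.frame(group = rownames(counts), wt = counts[, "wt"],
                         ko = counts[, "ko"], stringsAsFactors = FALSE)
  for (col in c("group", "wt", "ko"))
    if (!col %in% names(counts)) stopf("counts lacks column '%s'", col)
  counts <- counts[!counts$group %in% exclude, , drop = FALSE]
  zero_wt <- counts$wt == 0
  if (any(zero_wt)) {
    warnf("excluding group(s) with zero wt cells: %s",
          paste(counts$group[zero_wt], collapse = ", "))
    counts <- counts[!zero_wt, , drop = FALSE]
  }
  n <- nrow(counts)
  if (n < 2) stopf("need >= 2 groups with wt cells; have %d", n)
  fold <- counts$ko / counts$wt
  m <- mean(fold); s <- stats::sd(fold)
  upper <- m + stats::qt((1 + level) / 2, df = n - 1) * s / sqrt(n)
  tab <- data.frame(group = counts$group, wt = counts$wt, ko = counts$ko,
                    fold = fold, flagged = fold > upper,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, mean_fold = m, sd_fold = s,
                 upper_limit = upper, level = level, n = n),
            class = "expansion_table")
}

#' @export
print.expansion_table <- function(x, ...) {
  cat(sprintf("expansion over %d groups: mean fold %.3f, SD %.3f, %g%% CI upper limit %.3f\n",
              x$n, x$mean_fold, x$sd_fold, 100 * x$level, x$upper_limit))
  print(x$table)
  invisible(x)
}

#' Construct a positivity rule
#'
#' Three rule kinds: `gt_zero` (expression strictly above zero, the mitotic
#' and tip marker convention), `gt_q1` (strictly above the first quartile of
#' the marker over a stated reference population, the progenitor marker
#' convention; the quartile is computed once, zeros included, type-7 linear
#' interpolation), and `gt_threshold` (a fixed cutoff).
#'
#' @param kind one of `"gt_zero"`, `"gt_q1"`, `"gt_threshold"`.
#' @param threshold cutoff for `gt_threshold`.
#' @return object of class `positivity_rule`.
#' @export
positivity_rule <- function(kind = c("gt_zero", "gt_q1", "gt_threshold"),
                            threshold = NULL) {
  kind <- match.arg(kind)
  if (kind == "gt_threshold" && (is.null(threshold) || !is.numeric(threshold)))
    stopf("gt_threshold rule needs a numeric threshold")
  structure(list(kind = kind, threshold = threshold), class = "positivity_rule")
}

#' Per-cell positivity under a rule
#'
#' @param norm a `NormalizedMatrix`.
#' @param gene gene symbol; an absent gene is an error naming it.
#' @param rule a [positivity_rule()].
#' @param reference for `gt_q1`: logical or integer subset defining the
#'   reference population over which Q1 is computed (default: all cells).
#' @return logical vector, one entry per cell. The cutoff actually used is
#'   attached as `attr(, "cutoff")`.
#' @export
positive_cells <- function(norm, gene, rule = positivity_rule("gt_zero"),
                           reference = NULL) {
  j <- match(gene, norm$gene_meta$gene)
  if (is.na(j)) stopf("gene '%s' not present in the matrix", gene)
  vals <- as.numeric(norm$values[, j])
  cutoff <- switch(rule$kind,
    gt_zero = 0,
    gt_threshold = rule$threshold,
    gt_q1 = {
      ref <- if (is.null(reference)) vals else vals[reference]
      if (length(ref) == 0) stopf("empty reference population for Q1")
      unname(stats::quantile(ref, 0.25, type = 7))
    })
  structure(vals > cutoff, cutoff = cutoff)
}

#' Positivity fractions by group and genotype, with CI-flagged folds
#'
#' Computes the fraction of positive cells per group and genotype, the
#' knockout-over-wild-type fold of those fractions per group, and applies the
#' same t-interval flagging as [expansion_fold()]. Groups with a zero
#' wild-type fraction are excluded with a warning.
#'
#' @param positives logical vector from [positive_cells()].
#' @param groups group (cluster or branch) label per cell.
#' @param genotypes genotype per cell (`"wt"`/`"ko"`).
#' @param level confidence level (default 0.95).
#' @return list: `fractions` (group, genotype, n, n_pos, fraction) and
#'   `expansion` (an `expansion_table` over the fraction folds; counts columns
#'   hold the fractions).
#' @export
positivity_fraction_fold <- function(positives, groups, genotypes,
                                     level = 0.95) {
  stopifnot(length(positives) == length(groups),
            length(groups) == length(genotypes))
  agg <- expand.grid(group = sort(unique(groups)), genotype = c("wt", "ko"),
                     stringsAsFactors = FALSE)
  agg$n <- mapply(function(g, gt) sum(groups == g & genotypes == gt),
                  agg$group, agg$genotype)
  agg$n_pos <- mapply(function(g, gt)
    sum(positives & groups == g & genotypes == gt), agg$group, agg$genotype)
  agg$fraction <- ifelse(agg$n > 0, agg$n_pos / agg$n, NA_real_)
  wt <- agg[agg$genotype == "wt", ]
  ko <- agg[agg$genotype == "ko", ]
  fr <- data.frame(group = wt$group, wt = wt$fraction,
                   ko = ko$fraction[match(wt$group, ko$group)],
                   stringsAsFactors = FALSE)
  fr <- fr[!is.na(fr$wt) & !is.na(fr$ko), ]
  exp_tab <- expansion_fold(fr, level = level)
  list(fractions = agg, expansion = exp_tab)
}

#' Cells positive under two rules at once
#'
#' Counts cells positive for both genes under their respective rules, per
#' group and genotype (e.g. Mki67-positive progenitor-marker-positive cells
#' per trajectory branch).
#'
#' @param norm a `NormalizedMatrix`.
#' @param gene_a,gene_b gene symbols.
#' @param rule_a,rule_b [positivity_rule()]s for each gene.
#' @param groups,genotypes per-cell labels.
#' @param reference_a,reference_b Q1 reference populations where applicable.
#' @return data frame (group, genotype, n, n_double_pos).
#' @export
double_positive_counts <- function(norm, gene_a, gene_b,
                                   rule_a = positivity_rule("gt_q1"),
                                   rule_b = positivity_rule("gt_zero"),
                                   groups, genotypes,
                                   reference_a = NULL, reference_b = NULL) {
  pa <- positive_cells(norm, gene_a, rule_a, reference_a)
  pb <- positive_cells(norm, gene_b, rule_b, reference_b)
  both <- pa & pb
  agg <- expand.grid(group = sort(unique(groups)), genotype = c("wt", "ko"),
                     stringsAsFactors = FALSE)
  agg$n <- mapply(function(g, gt) sum(groups == g & genotypes == gt),
                  agg$group, agg$genotype)
  agg$n_double_pos <- mapply(function(g, gt)
    sum(both & groups == g & genotypes == gt), agg$group, agg$genotype)
  agg
}

#' Load externally computed trajectory branch assignments
#'
#' Branch assignments (e.g. from a trajectory-inference tool, branches named
#' by their connected points such as `S0-S1`) are consumed as a grouping
#' usable wherever clusters are.
#'
#' @param table data frame or TSV path with columns `cell_id`, `branch`.
#' @param cell_ids optional vector of expected cell ids; unknown ids in the
#'   table raise an error listing them.
#' @return named character vector, cell id -> branch.
#' @export
load_branches <- function(table, cell_ids = NULL) {
  if (is.character(table)) table <- read_tsv(table)
  for (col in c("cell_id", "branch"))
    if (!col %in% names(table)) stopf("branch table lacks column '%s'", col)
  dup <- unique(table$cell_id[duplicated(table$cell_id)])
  if (length(dup))
    stopf("duplicate cell id(s) in branch table: %s",
          paste(utils::head(dup, 5), collapse = ", "))
  if (!is.null(cell_ids)) {
    unknown <- setdiff(table$cell_id, cell_ids)
    if (length(unknown))
      stopf("branch table names unknown cell(s): %s",
            paste(utils::head(unknown, 5), collapse = ", "))
  }
  stats::setNames(as.character(table$branch), table$cell_id)
}
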