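## Spot classification by conjunctive co-expression thresholds on normalized
## values, and the Fisher exact comparison of proliferating-spot proportions
## between spot classes after merging the knockout samples.

#' Default spot classification rules
#'
#' Conjunctive rules on log-normalized spot values. Endothelial (EC) spots
#' co-express Cldn5, Cdh5 and Pecam1 above `ec_thresh`; lesion adds Klf4,
#' Klf2, Ly6a and Thbd; tip adds Apln and Plaur; proliferating variants add
#' Mki67 above `mki67_thresh`. Because each flag's gene set contains the EC
#' set, the flag implication hierarchy holds by construction.
#'
#' @param ec_thresh threshold for identity/lesion/tip genes (default 0.5).
#' @param mki67_thresh threshold for Mki67 (default 1).
#' @return named list: flag -> data frame (gene, threshold).
#' @export
default_spot_rules <- function(ec_thresh = 0.5, mki67_thresh = 1) {
  ec <- data.frame(gene = c("Cldn5", "Cdh5", "Pecam1"), threshold = ec_thresh,
                   stringsAsFactors = FALSE)
  lesion <- rbind(ec, data.frame(gene = c("Klf4", "Klf2", "Ly6a", "Thbd"),
                                 threshold = ec_thresh))
  tip <- rbind(ec, data.frame(gene = c("Apln", "Plaur"),
                              threshold = ec_thresh))
  tip_lesion <- rbind(lesion, data.frame(gene = c("Apln", "Plaur"),
                                         threshold = ec_thresh))
  mki <- data.frame(gene = "Mki67", threshold = mki67_thresh)
  list(ec = ec,
       proliferating_ec = rbind(ec, mki),
       lesion_ec = lesion,
       proliferating_lesion_ec = rbind(lesion, mki),
       tip_ec = tip,
       tip_lesion_ec = tip_lesion,
       proliferating_tip_ec = rbind(tip, mki),
       proliferating_tip_lesion_ec = rbind(tip_lesion, mki))
}

#' Classify spots by co-expression threshold rules
#'
#' Applies each rule's conjunction (`value > threshold` for every gene in the
#' rule) to the normalized spot values.
#'
#' @param norm_spots a `NormalizedMatrix` of kind `"spots"` (from
#'   [lognormalize()] on a [spot_matrix()]).
#' @param rules a rule table, e.g. [default_spot_rules()].
#' @return data frame with `spot_id` and one logical column per flag.
#' @export
classify_spots <- function(norm_spots, rules = default_spot_rules()) {
  genes_needed <- unique(unlist(lapply(rules, `[[`, "gene")))
  missing <- setdiff(genes_needed, norm_spots$gene_meta$gene)
  if (length(missing))
    stopf("rule gene(s) missing from the matrix: %s",
          paste(missing, collapse = ", "))
  v <- norm_spots$values
  flags <- lapply(rules, function(rule) {
    ok <- rep(TRUE, nrow(v))
    for (i in seq_len(nrow(rule))) {
      j <- match(rule$gene[i], norm_spots$gene_meta$gene)
      ok <- ok & as.numeric(v[, j]) > rule$threshold[i]
    }
    ok
  })
  out <- data.frame(spot_id = norm_spots$cell_meta$spot_id,
                    stringsAsFactors = FALSE)
  for (nm in names(flags)) out[[nm]] <- flags[[nm]]
  out
}

#' Fisher exact comparison of proliferating proportions between spot classes
#'
#' Rows of the 2x2 table are spots in `class_a` but not `class_b` versus
#' spots in `class_b` (disjoint rows; set `nested = TRUE` to use all of
#' `class_a` instead); columns are the corresponding proliferating flag yes /
#' no. Samples are merged before counting (restrict `flags` beforehand to
#' merge only the knockout samples). Two-sided p by the point-probability
#' method.
#'
#' @param flags a [classify_spots()] data frame.
#' @param class_a,class_b flag column names (defaults `"ec"`, `"lesion_ec"`).
#' @param nested keep `class_b` spots inside the `class_a` row (default
#'   FALSE).
#' @return list: `table` (2x2 matrix), `p` (two-sided Fisher exact),
#'   `proportions` per class.
#' @export
proliferation_fisher <- function(flags, class_a = "ec",
                                 class_b = "lesion_ec", nested = FALSE) {
  event_a <- paste0("proliferating_", class_a)
  event_b <- paste0("proliferating_", class_b)
  for (col in c(class_a, class_b, event_a, event_b))
    if (!col %in% names(flags)) stopf("flags lack column '%s'", col)
  in_a <- flags[[class_a]] & (nested | !flags[[class_b]])
  in_b <- flags[[class_b]]
  if (sum(in_a) == 0 || sum(in_b) == 0)
    stopf("empty spot class (%s: %d, %s: %d)", class_a, sum(in_a), class_b,
          sum(in_b))
  ev_a <- flags[[event_a]][in_a]
  ev_b <- flags[[event_b]][in_b]
  tab <- matrix(c(sum(ev_a), sum(!ev_a), sum(ev_b), sum(!ev_b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c(class_a, class_b), c("event", "no_event")))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(table = tab, p = p,
       proportions = stats::setNames(c(mean(ev_a), mean(ev_b)),
                                     c(class_a, class_b)))
}

#' Per-spot expression table of one gene for overlay mapping
#'
#' @param norm_spots a `NormalizedMatrix` of kind `"spots"`.
#' @param gene gene symbol.
#' @param path optional TSV output path.
#' @return data frame (spot_id, x, y, value).
#' @export
spot_gene_overlay <- function(norm_spots, gene, path = NULL) {
  j <- match(gene, norm_spots$gene_meta$gene)
  if (is.na(j)) stopf("gene '%s' not present in the matrix", gene)
  df <- data.frame(spot_id = norm_spots$cell_meta$spot_id,
                   x = norm_spots$cell_meta$x, y = norm_spots$cell_meta$y,
                   value = as.numeric(norm_spots$values[, j]),
                   stringsAsFactors = FALSE)
  if (!is.null(path)) write_tsv(df, path)
  df
}
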