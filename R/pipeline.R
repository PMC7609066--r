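## End-to-end orchestration from a single JSON configuration: simulate (or
## read) -> QC -> normalize -> cluster scan -> resolution selection ->
## markers/annotation -> DEG/uniqueness -> expansion/positivity -> enrichment
## -> spots. Every stage's parameters default to the study's stated settings;
## all randomness flows from one seed; a manifest records parameters, seed
## and output hashes.

pipeline_defaults <- function() {
  list(
    inputs = list(cells_mtx_dir = NULL, cells_tsv = NULL, cell_meta_tsv = NULL,
                  spots_tsv = NULL, panel_tsv = NULL, gmt = NULL,
                  branches_tsv = NULL, embedding_tsv = NULL),
    simulate = list(enabled = TRUE, n_clusters = 8L, cells_per_cluster = 150L,
                    n_genes = 1000L, marker_fold = 8, spots = TRUE,
                    n_spots = 300L),
    qc = list(sd_k = 2, mito_max = 0.05),
    normalize = list(scale = 1e4),
    variable_genes = list(n_top = 500L),
    cluster = list(n_pcs = 30L, neighbors_k = 20L,
                   resolutions = c(0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5,
                                   0.6, 0.7, 0.8, 0.9, 1)),
    tree = list(identity_threshold = 0.9, low_inprop = 0.1, min_parents = 2L),
    markers = list(min_fraction = 0.1, annotate_logfc_min = 0,
                   annotate_p_max = 0.05, annotate_share = 0.5,
                   unique_logfc_min = 0.25, unique_p_max = 0.05,
                   unique_deg_logfc_min = 0.2, unique_deg_p_max = 0.05),
    expansion = list(level = 0.95, exclude = character(0)),
    positivity = list(
      mitotic_genes = c("Mki67", "Plk1", "Mxd3", "Birc5", "Ube2c"),
      tip_genes = c("Plaur", "Apln", "Mmrn2"),
      progenitor_genes = c("Bst1", "Peg3", "Procr", "Cd200")),
    enrich = list(p_max = 0.05, q_max = 0.25, q_dir = "le", odds_min = 4,
                  min_overlap = 2, input_lfc = 0.3),
    spots = list(ec_thresh = 0.5, mki67_thresh = 1),
    seed = 0L,
    outdir = "ccmEC_out")
}

merge_config <- function(defaults, user, path = "", errors) {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      errors$msgs <- c(errors$msgs, sprintf("unknown key '%s'", full))
      next
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        errors$msgs <- c(errors$msgs,
                         sprintf("'%s' must be a mapping", full))
      } else {
        defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full,
                                        errors)
      }
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Fills defaults, rejects unknown keys, range-checks values and aggregates
#' all errors rather than stopping at the first. An empty input yields the
#' full default configuration.
#'
#' @param config path to a JSON file, a list, or `NULL` for pure defaults.
#' @return normalized configuration list (class `pipeline_config`).
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    config <- if (file.size(config) == 0) list() else
      jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  config <- config %||% list()
  errors <- new.env()
  errors$msgs <- character(0)
  cfg <- merge_config(pipeline_defaults(), config, "", errors)

  chk <- function(ok, msg) if (!isTRUE(ok))
    errors$msgs <- c(errors$msgs, msg)
  chk(cfg$qc$mito_max >= 0 && cfg$qc$mito_max <= 1,
      sprintf("qc.mito_max = %g out of range [0, 1]", cfg$qc$mito_max))
  chk(cfg$qc$sd_k > 0, "qc.sd_k must be > 0")
  chk(cfg$normalize$scale > 0, "normalize.scale must be > 0")
  chk(cfg$cluster$n_pcs >= 1, "cluster.n_pcs must be >= 1")
  chk(cfg$markers$min_fraction >= 0 && cfg$markers$min_fraction <= 1,
      "markers.min_fraction out of range [0, 1]")
  chk(cfg$expansion$level > 0 && cfg$expansion$level < 1,
      "expansion.level must be in (0, 1)")
  chk(length(cfg$cluster$resolutions) >= 1,
      "cluster.resolutions must be non-empty")
  if (is.unsorted(cfg$cluster$resolutions, strictly = TRUE)) {
    warnf("cluster.resolutions not strictly ascending; sorting")
    cfg$cluster$resolutions <- sort(unique(cfg$cluster$resolutions))
  }
  if (length(errors$msgs))
    stopf("invalid configuration:\n  %s",
          paste(errors$msgs, collapse = "\n  "))
  structure(cfg, class = c("pipeline_config", "list"))
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate (optional) -> QC -> normalize -> cluster scan ->
#' resolution selection -> markers/annotation -> DEG/uniqueness ->
#' expansion/positivity -> enrichment (if gene sets given) -> spots (if spot
#' input or simulated). Writes every stage's table under `config$outdir` and
#' returns a manifest with parameters, seed and output md5 hashes. Stage
#' failures abort with the stage name; partial outputs are retained.
#'
#' @param config a [validate_config()] result, a list, or a JSON path.
#' @param stages character vector of stages to run (default all).
#' @return manifest list (also written to `manifest.json` in the outdir).
#' @export
run_pipeline <- function(config = NULL,
                         stages = c("simulate", "qc", "cluster", "annotate",
                                    "compare", "expand", "positivity",
                                    "enrich", "spots")) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "ccmEC",
                   version = as.character(utils::packageVersion("ccmEC")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = cfg$seed, parameters = unclass(cfg),
                   stages_run = character(0), skipped = character(0),
                   outputs = list())
  out_file <- function(name) file.path(cfg$outdir, name)
  note_output <- function(name) {
    manifest$outputs[[name]] <<- unname(tools::md5sum(out_file(name)))
  }

  truth <- NULL
  if (!is.null(cfg$inputs$cells_mtx_dir)) {
    counts <- stage_try("read", read_mtx_triplet(
      file.path(cfg$inputs$cells_mtx_dir, "matrix.mtx"),
      file.path(cfg$inputs$cells_mtx_dir, "barcodes.tsv"),
      file.path(cfg$inputs$cells_mtx_dir, "features.tsv"),
      cfg$inputs$cell_meta_tsv %||%
        file.path(cfg$inputs$cells_mtx_dir, "cell_meta.tsv")))
  } else if (!is.null(cfg$inputs$cells_tsv)) {
    counts <- stage_try("read", read_counts_tsv(cfg$inputs$cells_tsv,
                                                cfg$inputs$cell_meta_tsv))
  } else if ("simulate" %in% stages && isTRUE(cfg$simulate$enabled)) {
    sim <- stage_try("simulate", {
      sc <- sim_config(n_clusters = cfg$simulate$n_clusters,
                       cells_per_cluster_wt = rep(cfg$simulate$cells_per_cluster,
                                                  cfg$simulate$n_clusters),
                       expansion_factor_ko =
                         default_expansions(cfg$simulate$n_clusters),
                       n_genes = cfg$simulate$n_genes,
                       marker_fold = cfg$simulate$marker_fold,
                       seed = cfg$seed)
      simulate_cells(sc)
    })
    counts <- sim$counts
    truth <- sim$truth
    write_tsv(truth$cells, out_file("truth_cells.tsv"))
    note_output("truth_cells.tsv")
    manifest$stages_run <- c(manifest$stages_run, "simulate")
  } else {
    stopf("no cell input configured and simulation disabled")
  }

  qc <- stage_try("qc", qc_filter(counts, cfg$qc$sd_k, cfg$qc$mito_max))
  write_tsv(qc$report$per_cell, out_file("qc_report.tsv"))
  note_output("qc_report.tsv")
  manifest$stages_run <- c(manifest$stages_run, "qc")
  manifest$qc_removed <- as.list(qc$report$removed)

  norm <- stage_try("normalize", lognormalize(qc$counts,
                                              cfg$normalize$scale))
  scaled <- stage_try("normalize", regress_covariate(norm))
  hv <- stage_try("normalize", variable_genes(
    norm, min(cfg$variable_genes$n_top, ncol(norm$values))))

  embedding <- NULL
  if (!is.null(cfg$inputs$embedding_tsv)) {
    emb_df <- read_tsv(cfg$inputs$embedding_tsv)
    embedding <- as.matrix(emb_df[match(norm$cell_meta$cell_id,
                                        emb_df$cell_id), -1])
  }
  hv_idx <- match(hv, scaled$gene_meta$gene)
  scan <- stage_try("cluster", cluster_scan(
    scaled$values[, hv_idx, drop = FALSE],
    resolutions = cfg$cluster$resolutions,
    n_pcs = min(cfg$cluster$n_pcs, length(hv), nrow(scaled$values)),
    neighbors_k = cfg$cluster$neighbors_k,
    seed = cfg$seed, embedding = embedding))
  tree <- stage_try("cluster", build_cluster_tree(scan))
  report <- stage_try("cluster", select_resolution(
    tree, cfg$tree$identity_threshold, cfg$tree$low_inprop,
    cfg$tree$min_parents))
  clusters <- scan[, as.character(report$selected_resolution)]
  write_tsv(data.frame(cell_id = norm$cell_meta$cell_id, cluster = clusters),
            out_file("clusters.tsv"))
  note_output("clusters.tsv")
  jsonlite::write_json(
    list(stable_regions = report$stable_regions,
         overclustered_onset = report$overclustered_onset,
         selected_resolution = report$selected_resolution,
         n_clusters = report$n_clusters),
    out_file("region_report.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  note_output("region_report.json")
  manifest$stages_run <- c(manifest$stages_run, "cluster")
  manifest$selected_resolution <- report$selected_resolution
  manifest$n_clusters <- report$n_clusters

  if ("annotate" %in% stages) {
    markers <- stage_try("annotate", suppressWarnings(
      conserved_markers(norm, clusters, cfg$markers$min_fraction)))
    write_tsv(markers, out_file("markers.tsv"))
    note_output("markers.tsv")
    panel <- if (!is.null(cfg$inputs$panel_tsv))
      read_tsv(cfg$inputs$panel_tsv)
    else if (!is.null(truth)) truth_key_panel(truth) else NULL
    if (!is.null(panel) && nrow(markers) > 0) {
      ann <- stage_try("annotate", annotate_clusters(
        markers, panel, cfg$markers$annotate_logfc_min,
        cfg$markers$annotate_p_max, cfg$markers$annotate_share))
      write_tsv(ann, out_file("annotation.tsv"))
      note_output("annotation.tsv")
    }
    umk <- stage_try("annotate", unique_markers(
      markers, cfg$markers$unique_logfc_min, cfg$markers$unique_p_max))
    write_tsv(umk, out_file("unique_markers.tsv"))
    note_output("unique_markers.tsv")
    manifest$stages_run <- c(manifest$stages_run, "annotate")
  }

  deg <- NULL
  if ("compare" %in% stages) {
    deg <- stage_try("compare", suppressWarnings(
      deg_ko_vs_wt(norm, clusters)))
    write_tsv(deg$degs, out_file("degs.tsv"))
    write_tsv(deg$summary, out_file("deg_summary.tsv"))
    note_output("degs.tsv"); note_output("deg_summary.tsv")
    udeg <- stage_try("compare", unique_degs(
      deg$degs, cfg$markers$unique_deg_logfc_min,
      cfg$markers$unique_deg_p_max))
    write_tsv(udeg, out_file("unique_degs.tsv"))
    note_output("unique_degs.tsv")
    manifest$stages_run <- c(manifest$stages_run, "compare")
  }

  if ("expand" %in% stages) {
    gt <- norm$cell_meta$genotype
    cnts <- data.frame(group = sort(unique(clusters)))
    cnts$wt <- vapply(cnts$group, function(g)
      sum(clusters == g & gt == "wt"), numeric(1))
    cnts$ko <- vapply(cnts$group, function(g)
      sum(clusters == g & gt == "ko"), numeric(1))
    expt <- stage_try("expand", suppressWarnings(expansion_fold(
      cnts, cfg$expansion$level, cfg$expansion$exclude)))
    write_tsv(cbind(expt$table, upper_limit = expt$upper_limit),
              out_file("expansion.tsv"))
    note_output("expansion.tsv")
    manifest$stages_run <- c(manifest$stages_run, "expand")
  }

  if ("positivity" %in% stages) {
    gt <- norm$cell_meta$genotype
    pos_rows <- list()
    pos_spec <- list(gt_zero = c(cfg$positivity$mitotic_genes,
                                 cfg$positivity$tip_genes),
                     gt_q1 = cfg$positivity$progenitor_genes)
    for (kind in names(pos_spec)) {
      for (g in intersect(pos_spec[[kind]], norm$gene_meta$gene)) {
        pos <- positive_cells(norm, g, positivity_rule(kind))
        agg <- stats::aggregate(pos, by = list(cluster = clusters,
                                               genotype = gt), FUN = mean)
        names(agg)[3] <- "fraction"
        agg$gene <- g; agg$rule <- kind
        pos_rows[[paste(kind, g)]] <- agg
      }
    }
    if (length(pos_rows)) {
      write_tsv(do.call(rbind, pos_rows), out_file("positivity.tsv"))
      note_output("positivity.tsv")
    }
    manifest$stages_run <- c(manifest$stages_run, "positivity")
  }

  if ("enrich" %in% stages && !is.null(cfg$inputs$gmt) && !is.null(deg)) {
    sets <- stage_try("enrich", read_gmt(cfg$inputs$gmt))
    coll <- geneset_collection(sets, norm$gene_meta$gene)
    enr <- list()
    for (cl in unique(deg$degs$cluster)) {
      d <- deg$degs[deg$degs$cluster == cl, ]
      query <- d$gene[abs(d$logFC) >= cfg$enrich$input_lfc &
                        d$padj < cfg$markers$unique_deg_p_max]
      if (length(query) == 0) next
      e <- stage_try("enrich", suppressWarnings(overlap_enrichment(
        query, coll, cfg$enrich$p_max, cfg$enrich$q_max, cfg$enrich$q_dir,
        cfg$enrich$odds_min, cfg$enrich$min_overlap)))
      e$cluster <- cl
      enr[[as.character(cl)]] <- e
    }
    if (length(enr)) {
      write_tsv(do.call(rbind, enr), out_file("enrichment.tsv"))
      note_output("enrichment.tsv")
    }
    manifest$stages_run <- c(manifest$stages_run, "enrich")
  } else if ("enrich" %in% stages) {
    manifest$skipped <- c(manifest$skipped, "enrich")
  }

  spots <- NULL
  if ("spots" %in% stages) {
    if (!is.null(cfg$inputs$spots_tsv)) {
      spots <- stage_try("spots", read_spots_tsv(cfg$inputs$spots_tsv))
    } else if (!is.null(truth) && isTRUE(cfg$simulate$spots)) {
      ssim <- stage_try("spots", simulate_spots(
        truth$config, n_spots = cfg$simulate$n_spots))
      spots <- ssim$spots
      write_tsv(ssim$truth, out_file("truth_spots.tsv"))
      note_output("truth_spots.tsv")
    }
    if (!is.null(spots)) {
      nsp <- stage_try("spots", lognormalize(spots, cfg$normalize$scale))
      flags <- stage_try("spots", classify_spots(nsp, default_spot_rules(
        cfg$spots$ec_thresh, cfg$spots$mki67_thresh)))
      write_tsv(flags, out_file("spot_flags.tsv"))
      note_output("spot_flags.tsv")
      ko_flags <- flags[nsp$cell_meta$genotype == "ko", , drop = FALSE]
      if (sum(ko_flags$lesion_ec) > 0 &&
          sum(ko_flags$ec & !ko_flags$lesion_ec) > 0) {
        fish <- stage_try("spots", proliferation_fisher(ko_flags))
        jsonlite::write_json(list(table = fish$table, p = fish$p),
                             out_file("spot_fisher.json"), digits = NA,
                             auto_unbox = TRUE)
        note_output("spot_fisher.json")
      }
      manifest$stages_run <- c(manifest$stages_run, "spots")
    } else {
      manifest$skipped <- c(manifest$skipped, "spots")
    }
  }

  jsonlite::write_json(manifest, out_file("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `qc`, `cluster`, `annotate`, `compare`, `expand`,
#' `positivity`, `enrich`, `spots`, `run-all`; options `--config <path>`,
#' `--seed <int>`, `--outdir <dir>`. Earlier stages a subcommand depends on
#' are run as needed.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return manifest list, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  subcommands <- c("simulate", "qc", "cluster", "annotate", "compare",
                   "expand", "positivity", "enrich", "spots", "run-all")
  if (length(args) == 0 || !args[1] %in% subcommands)
    stopf("usage: ccmec <%s> [--config path] [--seed int] [--outdir dir]",
          paste(subcommands, collapse = "|"))
  sub <- args[1]
  opt <- list(config = NULL, seed = NULL, outdir = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args))
      stopf("unknown or valueless option: %s", args[i])
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  cfg <- validate_config(opt$config)
  if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
  if (!is.null(opt$outdir)) cfg$outdir <- opt$outdir
  stages <- if (sub == "run-all")
    c("simulate", "qc", "cluster", "annotate", "compare", "expand",
      "positivity", "enrich", "spots") else
    unique(c("simulate", "qc", "cluster", sub))
  run_pipeline(cfg, stages = stages)
}
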