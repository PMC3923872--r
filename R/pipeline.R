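# Orchestration: chains simulate -> hcne-cluster -> cpg -> chip ->
# bivalent -> states -> classify -> report over one configuration, with
# per-stage error reporting and a checksummed artifact manifest.

#' Pipeline parameter defaults
#'
#' Collects the analysis constants used across stages: locus flank 2 Mb
#' (HCNE windows), CpG flank 1 kb, promoter windows +/-10 kb, midpoint
#' windows +/-20 kb, enhancer profile +/-50 kb; bootstrap widths 10 kb /
#' 1 Mb / 2 Mb with B = 1000 and the 0.95 quantile; RPKM threshold 0.3;
#' fragment size 200; k = 2 clusters; bivalency quantile 0.75.
#'
#' @param seed integer seed forwarded to every stochastic stage.
#' @param ... overrides for any listed field.
#' @return a named list of parameters.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(seed = as.integer(seed), hcne_flank = 2e6, cpg_flank = 1000,
              promoter_flank = 1e4, midpoint_flank = 2e4,
              enhancer_profile_flank = 5e4,
              bootstrap_widths = c(1e4, 1e6, 2e6), B = 1000L,
              quantile = 0.95, rpkm_threshold = 0.3,
              fragment_size = 200L, k = 2L, bivalency_quantile = 0.75,
              profile_bin_small = 100, profile_bin_large = 1000)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) stop("unknown pipeline parameter(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(override)] <- override
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full GRB classification pipeline on synthetic data
#'
#' Chains every stage over one simulated dataset: HCNE count matrix,
#' dissimilarity and complete-linkage clustering; CpG summary with the
#' cluster rank-sum comparison (island-free genes excluded); bootstrap
#' enrichment calls for the enhancer mark at each width; promoter
#' bivalency classification in the stem line; chromatin-state counting
#' with two-way clustering; multi-target locus detection and resolution;
#' and the final per-gene target calls compared against the planted
#' truth. When `out_dir` is given, every stage writes its tab-delimited
#' output there ('#'-prefixed header comments), the resolved configuration
#' is written as YAML, and a manifest lists all files with md5 checksums.
#'
#' @param sim_cfg a [sim_config()]; its seed drives the generator.
#' @param cfg a [pipeline_config()]; its seed drives the bootstrap.
#' @param out_dir optional output directory.
#' @return a `grb_pipeline` list with per-stage results: `sim`, `hcne`,
#'   `cpg`, `chip`, `bivalency`, `states`, `classification`, `report`
#'   (and `manifest` when writing).
#' @export
run_grb_pipeline <- function(sim_cfg = sim_config(),
                             cfg = pipeline_config(seed = sim_cfg$seed),
                             out_dir = NULL) {
  sim <- run_stage("simulate", simulate_grb_data(
    sim_cfg, dir = if (is.null(out_dir)) NULL else
      file.path(out_dir, "sim")))
  genes <- sim$genes
  stem <- sim_cfg$stem_cell_line

  hcne <- run_stage("hcne-cluster", {
    tracks <- lapply(sim$hcnes, filter_hcnes)
    mat <- build_count_matrix(genes, tracks, flank = cfg$hcne_flank)
    dis <- hcne_dissimilarity(mat)
    cl <- hcne_cluster(dis, mat, k = cfg$k)
    list(matrix = mat, dissimilarity = dis, clusters = cl,
         profiles = lapply(split(seq_len(nrow(genes)), cl$labels),
                           function(idx) cumulative_profile(
                             genes[idx, , drop = FALSE], tracks[[1L]],
                             flank = cfg$hcne_flank)))
  })
  labels <- hcne$clusters$labels

  cpg <- run_stage("cpg", {
    summary <- summarize_cpg(genes, sim$cpg, flank = cfg$cpg_flank)
    with_island <- summary$n_islands > 0
    l1 <- summary$total_island_length[labels[summary$gene_id] == 1 &
                                        with_island]
    l2 <- summary$total_island_length[labels[summary$gene_id] == 2 &
                                        with_island]
    test <- if (length(l1) && length(l2)) compare_lengths(l1, l2) else NULL
    list(summary = summary, test = test,
         curves = list(cluster1 = if (length(l1))
           cumulative_length_curve(l1) else NULL,
           cluster2 = if (length(l2)) cumulative_length_curve(l2) else NULL))
  })

  expr_calls <- run_stage("expression", call_expression(
    sim$rpkm, threshold = cfg$rpkm_threshold))

  chip <- run_stage("chip", {
    lib <- sim$reads[[paste0("H3K4me1:", stem)]]
    pool <- genes  # synthetic pool: the whole simulated gene universe
    sets <- split(genes$gene_id, labels)
    calls <- list()
    for (w in cfg$bootstrap_widths) {
      counts <- tss_window_counts(pool, lib, w)
      for (lab in names(sets)) {
        gs <- genes[genes$gene_id %in% sets[[lab]], , drop = FALSE]
        null <- bootstrap_null(pool, lib, w, B = cfg$B, n = nrow(gs),
                               seed = substream_seed(cfg$seed,
                                                     paste0("null", w)),
                               counts = counts)
        calls[[paste0("cluster", lab, "_w", w)]] <-
          enrichment_call(gs, lib, null, label = paste0("cluster", lab))
      }
    }
    k4me3_profile <- average_profile(
      genes[genes$gene_id %in% expressed_genes(expr_calls, stem), ,
            drop = FALSE],
      sim$reads[[paste0("H3K4me3:", stem)]], "tss",
      cfg$promoter_flank, cfg$profile_bin_small)
    list(calls = calls, k4me3_profile = k4me3_profile)
  })

  bivalency <- run_stage("bivalent", {
    k4 <- promoter_counts(genes, sim$reads[[paste0("H3K4me3:", stem)]],
                          cfg$promoter_flank)
    k27 <- promoter_counts(genes, sim$reads[[paste0("H3K27me3:", stem)]],
                           cfg$promoter_flank)
    rec <- data.frame(gene_id = genes$gene_id, k4me3 = unname(k4),
                      k27me3 = unname(k27),
                      rpkm = expr_calls$rpkm[genes$gene_id, stem],
                      stringsAsFactors = FALSE)
    classify_bivalency(rec, quantile = cfg$bivalency_quantile)
  })

  states <- run_stage("states", {
    sm <- state_counts(genes, sim$states, "tss", cfg$promoter_flank)
    tw <- two_way_cluster(sm, rpkm = stats::setNames(
      expr_calls$rpkm[, stem], rownames(expr_calls$rpkm)), k = cfg$k)
    list(matrix = sm, clustering = tw,
         agreement = partition_agreement(labels, tw$row_labels))
  })

  classification <- run_stage("classify", {
    c1 <- genes[labels[genes$gene_id] == 1, , drop = FALSE]
    loci <- if (nrow(c1)) find_multi_target_loci(c1, sim$hcnes,
                                                 cfg$hcne_flank) else NULL
    bivalent <- stats::setNames(bivalency$bivalent, bivalency$gene_id)
    stem_expr <- stats::setNames(expr_calls$expressed[, stem],
                                 rownames(expr_calls$expressed))
    calls <- finalize_calls(labels, loci, bivalent, stem_expr)
    truth <- sim$truth$genes
    acc <- mean(calls$final_target ==
                  truth$is_target[match(calls$gene_id, truth$gene_id)])
    list(loci = loci, calls = calls, truth_accuracy = acc)
  })

  report <- run_stage("report", {
    enr <- do.call(rbind, lapply(chip$calls, function(x)
      data.frame(gene_set = x$gene_set, width = x$width,
                 log2_mean = x$log2_mean, q95 = x$q95,
                 outside_critical = x$outside_critical)))
    rownames(enr) <- NULL
    list(
      n_cluster1 = sum(labels == 1), n_cluster2 = sum(labels == 2),
      hcne_recovery = partition_agreement(
        labels, stats::setNames(ifelse(sim$truth$genes$is_target, 1, 2),
                                sim$truth$genes$gene_id)),
      state_agreement = states$agreement,
      cpg_p_value = if (!is.null(cpg$test)) cpg$test$p_value else NA_real_,
      enrichment = enr,
      n_final_targets = sum(classification$calls$final_target),
      truth_accuracy = classification$truth_accuracy)
  })

  res <- list(sim = sim, hcne = hcne, cpg = cpg, expression = expr_calls,
              chip = chip, bivalency = bivalency, states = states,
              classification = classification, report = report,
              config = cfg)
  class(res) <- "grb_pipeline"
  if (!is.null(out_dir)) {
    res$manifest <- run_stage("write-output",
                              write_pipeline_output(res, out_dir))
  }
  res
}

write_pipeline_output <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  put <- function(df, fname, comment) {
    p <- file.path(out_dir, fname)
    write_tsv_commented(df, p, comment)
    paths[[fname]] <<- p
  }
  mat <- res$hcne$matrix
  put(data.frame(gene_id = mat$genes, mat$log2, check.names = FALSE),
      "hcne_log2_matrix.tsv", "log2 HCNE density per gene and species pair")
  put(data.frame(gene_id = names(res$hcne$clusters$labels),
                 cluster = unname(res$hcne$clusters$labels)),
      "hcne_clusters.tsv", "complete-linkage cluster labels (1 = high HCNE)")
  put(res$cpg$summary, "cpg_summary.tsv",
      c("CpG island accounting per gene",
        if (!is.null(res$cpg$test))
          sprintf("rank-sum p (cluster 1 vs 2, island-bearing genes): %g",
                  res$cpg$test$p_value)))
  put(res$report$enrichment, "enrichment_calls.tsv",
      "bootstrap enrichment calls, H3K4me1, stem line")
  put(res$bivalency, "bivalency.tsv",
      sprintf("promoter quadrants; thresholds k4=%.3f k27=%.3f",
              attr(res$bivalency, "k4_threshold"),
              attr(res$bivalency, "k27_threshold")))
  put(data.frame(gene_id = names(res$states$clustering$row_labels),
                 state_cluster = unname(res$states$clustering$row_labels)),
      "state_clusters.tsv", "two-way state-map clustering, gene labels")
  put(res$classification$calls, "target_calls.tsv",
      "final GRB target calls with evidence fields")
  yaml::write_yaml(res$config, file.path(out_dir, "config_resolved.yaml"))
  paths[["config_resolved.yaml"]] <- file.path(out_dir,
                                               "config_resolved.yaml")
  manifest <- data.frame(name = names(paths), path = unname(unlist(paths)),
                         md5 = unname(tools::md5sum(unlist(paths))),
                         stringsAsFactors = FALSE)
  write_tsv_commented(manifest, file.path(out_dir, "MANIFEST.tsv"),
                      paste("seed:", res$config$seed))
  manifest
}
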