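# Expression calls, bivalent-promoter quadrant classification, and
# chromatin-state count matrices with two-way clustering.

#' Call expression from an RPKM table
#'
#' A gene is called expressed in a cell line when its RPKM is strictly
#' greater than `threshold` (default 0.3, the background level; a value of
#' exactly 0.3 is therefore not expressed).
#'
#' @param rpkm_table data.frame with `gene_id` and one numeric column per
#'   cell line.
#' @param threshold RPKM call threshold (default 0.3).
#' @return an `expression_calls` list: `rpkm` (matrix), `expressed`
#'   (logical matrix), `threshold`, `cell_lines`.
#' @export
call_expression <- function(rpkm_table, threshold = 0.3) {
  stopifnot("gene_id" %in% names(rpkm_table))
  cells <- setdiff(names(rpkm_table), "gene_id")
  m <- as.matrix(rpkm_table[, cells, drop = FALSE])
  rownames(m) <- rpkm_table$gene_id
  structure(list(rpkm = m, expressed = m > threshold,
                 threshold = threshold, cell_lines = cells),
            class = "expression_calls")
}

#' Genes expressed (or silent) in one cell line
#' @param calls an [call_expression()] result.
#' @param cell_line cell line name.
#' @param expressed return expressed (`TRUE`) or silent (`FALSE`) genes.
#' @return character vector of gene ids.
#' @export
expressed_genes <- function(calls, cell_line, expressed = TRUE) {
  flag <- calls$expressed[, cell_line]
  rownames(calls$rpkm)[flag == expressed]
}

#' Library-normalized promoter tag counts
#'
#' Tags overlapping `[tss - flank, tss + flank)` per gene, scaled by
#' `1e6 / library_size` (0 for an empty library).
#'
#' @param genes a [gene_set()].
#' @param lib a [tag_library()].
#' @param flank promoter window half-width (default 10 kb).
#' @return named numeric vector.
#' @export
promoter_counts <- function(genes, lib, flank = 10000) {
  counts <- tss_window_counts(genes, lib, flank)
  if (lib$library_size == 0L) return(counts * 0)
  counts * 1e6 / lib$library_size
}

#' Classify promoters into bivalency quadrants
#'
#' Each gene carries normalized H3K4me3 and H3K27me3 promoter counts.
#' "High" means strictly above the mark's threshold; thresholds default to
#' the given quantile (0.75) of each mark's counts over a pooled background
#' set. Quadrants: `active-only` (K4 high, K27 low), `bivalent-active`
#' (both high), `poised` (K27 high only), `silent-unmarked` (both low).
#' The `bivalent` flag is K27-high — repression-mark presence on a promoter
#' that may also carry K4 — matching the operational use of the bivalent
#' domain when resolving multi-target loci.
#'
#' @param records data.frame with `gene_id`, `k4me3`, `k27me3` and
#'   optionally `rpkm`.
#' @param k4_threshold,k27_threshold explicit thresholds; when `NULL` they
#'   are the `quantile` of the background columns.
#' @param background data.frame with `k4me3`, `k27me3` columns used for
#'   threshold derivation (defaults to `records` itself).
#' @param quantile background quantile defining "high" (default 0.75).
#' @return `records` with added `k4_high`, `k27_high`, `quadrant`,
#'   `bivalent` columns; thresholds attached as attributes.
#' @export
classify_bivalency <- function(records, k4_threshold = NULL,
                               k27_threshold = NULL, background = records,
                               quantile = 0.75) {
  if (is.null(k4_threshold)) {
    k4_threshold <- stats::quantile(background$k4me3, quantile, names = FALSE)
  }
  if (is.null(k27_threshold)) {
    k27_threshold <- stats::quantile(background$k27me3, quantile,
                                     names = FALSE)
  }
  if (!is.finite(k4_threshold) || !is.finite(k27_threshold)) {
    stop("bivalency thresholds are not finite (empty background?)",
         call. = FALSE)
  }
  k4_high <- records$k4me3 > k4_threshold
  k27_high <- records$k27me3 > k27_threshold
  records$k4_high <- k4_high
  records$k27_high <- k27_high
  records$quadrant <- ifelse(
    k4_high & k27_high, "bivalent-active",
    ifelse(k4_high, "active-only",
           ifelse(k27_high, "poised", "silent-unmarked")))
  records$bivalent <- k27_high
  attr(records, "k4_threshold") <- k4_threshold
  attr(records, "k27_threshold") <- k27_threshold
  records
}

#' Per-gene chromatin-state count matrix
#'
#' Counts, within an anchored window around each gene, the bases covered
#' by each state of a labelled segmentation (`"bp"` mode, robust to
#' segment fragmentation) or the number of overlapping segments
#' (`"segments"` mode). When the segmentation tiles the genome, bp rows
#' sum to the window length. A `log2(count + 1)` companion matrix is
#' included.
#'
#' @param genes a [gene_set()].
#' @param segmentation `feature_track` whose `name` column holds state
#'   labels.
#' @param anchor window anchor (default `"tss"`).
#' @param flank window half-width (e.g. 1e4 or 1e5).
#' @param mode `"bp"` (default) or `"segments"`.
#' @return a `state_count_matrix` list: `counts`, `log2` (gene x state),
#'   `states`, `anchor`, `flank`, `mode`.
#' @export
state_counts <- function(genes, segmentation, anchor = "tss", flank = 1e4,
                         mode = c("bp", "segments")) {
  mode <- match.arg(mode)
  states <- sort(unique(segmentation$name))
  windows <- make_windows(genes, anchor, flank)
  m <- matrix(0, nrow(genes), length(states),
              dimnames = list(genes$gene_id, states))
  for (s in states) {
    sub <- segmentation[segmentation$name == s, , drop = FALSE]
    m[, s] <- if (mode == "bp") overlap_bp(windows, sub) else
      count_overlaps(windows, sub)
  }
  structure(list(counts = m, log2 = log2(m + 1), states = states,
                 anchor = anchor, flank = flank, mode = mode),
            class = "state_count_matrix")
}

#' Two-way clustering of the state count matrix
#'
#' Genes and columns are each clustered by complete linkage on Euclidean
#' distances of the log2 matrix; the gene dendrogram is cut at `k`.
#' Expression is joined in as one extra `RNA_seq` column of
#' `log2(rpkm + 1)` when supplied, so the column dendrogram can relate
#' states to transcription.
#'
#' @param state_mat a [state_counts()] result.
#' @param rpkm optional named vector of RPKM values (one per gene).
#' @param k number of gene clusters (default 2).
#' @return a `two_way_clustering` list: `matrix`, `row_labels` (named,
#'   cut at `k`), `row_order`, `col_order`, `row_hclust`, `col_hclust`.
#' @export
two_way_cluster <- function(state_mat, rpkm = NULL, k = 2) {
  M <- state_mat$log2
  if (!is.null(rpkm)) {
    M <- cbind(M, RNA_seq = log2(rpkm[rownames(M)] + 1))
  }
  if (k > nrow(M)) stop("k exceeds the number of genes", call. = FALSE)
  rhc <- stats::hclust(stats::dist(M), method = "complete")
  chc <- stats::hclust(stats::dist(t(M)), method = "complete")
  structure(list(matrix = M,
                 row_labels = stats::cutree(rhc, k = k),
                 row_order = rownames(M)[rhc$order],
                 col_order = colnames(M)[chc$order],
                 row_hclust = rhc, col_hclust = chc, k = k),
            class = "two_way_clustering")
}

#' Agreement between two 2-class partitions
#'
#' Fraction of items with identical labels under the best of the two
#' label matchings (cluster numbering is arbitrary).
#'
#' @param a,b named label vectors over the same items.
#' @return fraction in \[0, 1\].
#' @export
partition_agreement <- function(a, b) {
  common <- intersect(names(a), names(b))
  a <- a[common]; b <- b[common]
  max(mean(a == b), mean(a != b))
}
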