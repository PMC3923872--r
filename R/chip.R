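# Tag-based coverage profiles, library-size normalization, and the
# bootstrap background null for enhancer-mark enrichment.

#' Construct a ChIP tag library
#'
#' @param tags `feature_track` of 1 bp tag 5' positions with strand.
#' @param mark histone mark name (e.g. `"H3K4me1"`).
#' @param cell_line cell line name.
#' @param fragment_size fragment extension length in bp (default 200).
#' @return a `tag_library` list with `tags`, `library_size`,
#'   `fragment_size`, `mark`, `cell_line`.
#' @export
tag_library <- function(tags, mark = "mark", cell_line = "cell",
                        fragment_size = 200) {
  stopifnot(fragment_size > 0)
  structure(list(tags = tags, library_size = nrow(tags),
                 fragment_size = as.integer(fragment_size), mark = mark,
                 cell_line = cell_line),
            class = "tag_library")
}

#' Extend tags to fragment-sized intervals
#'
#' A `+` (or unstranded) tag at position p becomes `[p, p + f)`; a `-` tag
#' extends leftward and ends just past its 5' base: `[p + 1 - f, p + 1)`.
#' Starts are clipped at 0.
#'
#' @param lib a [tag_library()].
#' @return `feature_track` of extended fragments.
#' @export
extend_tags <- function(lib) {
  tr <- lib$tags
  f <- lib$fragment_size
  if (nrow(tr) == 0L) return(tr)
  minus <- tr$strand == "-"
  s <- ifelse(minus, tr$start + 1 - f, tr$start)
  e <- ifelse(minus, tr$start + 1, tr$start + f)
  s <- pmax(s, 0)
  feature_track(tr$chrom, s, pmax(e, s + 1), strand = tr$strand,
                label = track_label(tr))
}

#' Library-normalized binned coverage over a window
#'
#' Counts extended fragments overlapping each `bin`-bp bin of the window
#' and scales by `1e6 / library_size` (reads per million). An empty
#' library yields zeros.
#'
#' @param lib a [tag_library()].
#' @param chrom,start,end window coordinates (half-open).
#' @param bin bin width in bp; the window length should be a multiple.
#' @return numeric vector of reads-per-million per bin.
#' @export
binned_coverage <- function(lib, chrom, start, end, bin) {
  nb <- ceiling((end - start) / bin)
  if (lib$library_size == 0L) return(numeric(nb))
  frags <- extend_tags(lib)
  ti <- which(frags$chrom == chrom)
  if (length(ti) == 0L) return(numeric(nb))
  bs <- start + (seq_len(nb) - 1) * bin
  be <- pmin(bs + bin, end)
  counts <- IRanges::countOverlaps(as_iranges(bs, be),
                                   as_iranges(frags$start[ti],
                                              frags$end[ti]))
  as.numeric(counts) * 1e6 / lib$library_size
}

#' Average coverage profile over a gene set
#'
#' Unweighted mean of per-gene binned coverage vectors in anchored
#' windows; bin vectors of `-` strand genes are reversed so bins are in
#' anchor-relative (e.g. TSS-relative) orientation.
#'
#' @param genes a [gene_set()].
#' @param lib a [tag_library()].
#' @param anchor window anchor (see [make_windows()]).
#' @param flank window half-width in bp.
#' @param bin bin width in bp.
#' @return a `coverage_profile` list: `values` (per-bin reads per million),
#'   `positions` (bin starts relative to the anchor), `bin_size`, `anchor`,
#'   `flank`, `n_genes`, `mark`, `cell_line`.
#' @export
average_profile <- function(genes, lib, anchor = "tss", flank = 10000,
                            bin = 100) {
  windows <- make_windows(genes, anchor, flank)
  nb <- 2 * flank / bin
  acc <- numeric(nb)
  for (i in seq_len(nrow(windows))) {
    v <- binned_coverage(lib, windows$chrom[i], windows$start[i],
                         windows$end[i], bin)
    v <- c(numeric(nb - length(v)), v)  # left-pad windows clipped at 0
    if (windows$strand[i] == "-") v <- rev(v)
    acc <- acc + v
  }
  structure(list(values = acc / max(nrow(windows), 1L),
                 positions = seq(-flank, flank - bin, by = bin),
                 bin_size = bin, anchor = anchor, flank = flank,
                 n_genes = nrow(windows), mark = lib$mark,
                 cell_line = lib$cell_line),
            class = "coverage_profile")
}

#' Pool background and family genes into one background set
#'
#' Concatenates the two gene sets and de-duplicates by `gene_id`; the
#' result is sorted by `gene_id`, so it is independent of input order.
#'
#' @param background_genes,family_genes [gene_set()]s.
#' @return a [gene_set()].
#' @export
build_background_pool <- function(background_genes, family_genes) {
  df <- rbind(as.data.frame(background_genes)[, 1:6],
              as.data.frame(family_genes)[, 1:6])
  df <- df[!duplicated(df$gene_id), , drop = FALSE]
  df <- df[order(df$gene_id), , drop = FALSE]
  gene_set(df$gene_id, df$chrom, df$start, df$end, df$strand, df$symbol)
}

#' Raw tag counts in TSS-centred windows
#'
#' Counts unextended tag 5' positions overlapping
#' `[tss - width, tss + width)` per gene — the statistic fed to the
#' bootstrap null (fragment extension is used only for profile plots).
#'
#' @param genes a [gene_set()].
#' @param lib a [tag_library()].
#' @param width window half-width in bp.
#' @return named numeric vector of counts.
#' @export
tss_window_counts <- function(genes, lib, width) {
  windows <- make_windows(genes, "tss", width)
  stats::setNames(as.numeric(count_overlaps(windows, lib$tags)),
                  genes$gene_id)
}

#' Bootstrap background null for a window read-count statistic
#'
#' Draws `B` bootstrap samples of `n` genes (with replacement) from the
#' background pool; for each sample the statistic is
#' `log2(mean per-gene tag count + pseudocount)`. The critical region is
#' everything above the empirical 0.95-quantile (linear, type-7
#' interpolation) of these B values.
#'
#' @param pool background [gene_set()] (typically background genes pooled
#'   with the gene family, see [build_background_pool()]).
#' @param lib a [tag_library()].
#' @param width TSS window half-width in bp (e.g. 1e4, 1e6, 2e6).
#' @param B number of bootstrap samples (default 1000).
#' @param n genes per sample; defaults should match the size of the gene
#'   set whose enrichment is being evaluated.
#' @param seed RNG seed for the resampling.
#' @param pseudocount added inside the log2 (default 1).
#' @param counts optional precomputed [tss_window_counts()] for the pool.
#' @return a `bootstrap_null` list: `width`, `B`, `n`, `statistic_values`,
#'   `q95`, `seed`, `pseudocount`, `pool_counts`.
#' @export
bootstrap_null <- function(pool, lib, width, B = 1000, n, seed = 1,
                           pseudocount = 1, counts = NULL) {
  if (is.null(counts)) counts <- tss_window_counts(pool, lib, width)
  if (length(counts) == 0L) stop("empty background pool", call. = FALSE)
  stopifnot(n >= 1, B >= 1)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  idx <- matrix(sample.int(length(counts), B * n, replace = TRUE), nrow = B)
  stat <- log2(rowMeans(matrix(counts[idx], nrow = B)) + pseudocount)
  structure(list(width = width, B = B, n = n, statistic_values = stat,
                 q95 = unname(stats::quantile(stat, 0.95, type = 7)),
                 seed = seed, pseudocount = pseudocount,
                 pool_counts = counts),
            class = "bootstrap_null")
}

#' Evaluate a gene set against a bootstrap critical region
#'
#' Computes the same statistic as the null — `log2(mean per-gene count in
#' the TSS window + pseudocount)` over the full gene set — and flags
#' whether it falls outside (above) the 0.95-quantile critical value.
#'
#' @param genes the evaluated [gene_set()].
#' @param lib a [tag_library()].
#' @param null a [bootstrap_null()].
#' @param label gene-set label carried into the call.
#' @return an `enrichment_call` list: `gene_set`, `width`, `log2_mean`,
#'   `q95`, `outside_critical`, `n_genes`.
#' @export
enrichment_call <- function(genes, lib, null, label = "gene_set") {
  counts <- tss_window_counts(genes, lib, null$width)
  log2_mean <- log2(mean(counts) + null$pseudocount)
  structure(list(gene_set = label, width = null$width,
                 log2_mean = log2_mean, q95 = null$q95,
                 outside_critical = log2_mean > null$q95,
                 n_genes = length(counts)),
            class = "enrichment_call")
}

#' Partition genes by promoter CpG island presence
#'
#' A gene is a CpG gene when at least one island overlaps
#' `[tss - flank, tss + flank)` by >= 1 bp.
#'
#' @param genes a [gene_set()].
#' @param cpg_track CpG island `feature_track`.
#' @param flank TSS window half-width (default 1 kb).
#' @return list with [gene_set()]s `cpg` and `noncpg`.
#' @export
stratify_by_cpg <- function(genes, cpg_track, flank = 1000) {
  windows <- make_windows(genes, "tss", flank)
  has_cpg <- count_overlaps(windows, cpg_track) > 0
  list(cpg = genes[has_cpg, , drop = FALSE],
       noncpg = genes[!has_cpg, , drop = FALSE])
}

#' Filter called peaks by p-value and rank
#'
#' Keeps peaks with `pvalue < max_p`, then the `top_n` highest-scoring of
#' those (ties broken by genomic position for determinism).
#'
#' @param peaks a `feature_track` with a `pvalue` column (and `score`).
#' @param top_n maximum number of peaks retained (default 10000).
#' @param max_p p-value cutoff (default 0.001, strict `<`).
#' @return the filtered, position-sorted `feature_track`.
#' @export
filter_peaks <- function(peaks, top_n = 10000, max_p = 0.001) {
  if (is.null(peaks$pvalue)) stop("peaks require a 'pvalue' column",
                                  call. = FALSE)
  keep <- which(peaks$pvalue < max_p)
  if (length(keep) > top_n) {
    ord <- keep[order(-peaks$score[keep], peaks$chrom[keep],
                      peaks$start[keep])]
    keep <- sort(ord[seq_len(top_n)])
  }
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "label") <- attr(peaks, "label")
  class(out) <- class(peaks)
  out
}
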