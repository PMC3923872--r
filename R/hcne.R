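# Stage 1: per-gene HCNE feature matrix across species pairs, Euclidean
# dissimilarity on log2 densities, complete-linkage clustering into
# high-/low-HCNE classes, and cumulative positional profiles.

#' Filter an HCNE track by conservation cutoffs
#'
#' Retains elements whose percent identity is at least `min_identity` and
#' whose length is at least `min_length` (both inclusive). When cutoffs are
#' omitted they default to the track's own species-pair cutoffs, or to 0.
#'
#' @param track a `feature_track` whose `score` column is percent identity.
#' @param min_identity percent identity cutoff.
#' @param min_length length cutoff in bp.
#' @return the filtered `feature_track`.
#' @export
filter_hcnes <- function(track, min_identity = NULL, min_length = NULL) {
  sp <- attr(track, "species_pair")
  if (is.null(min_identity)) min_identity <- if (!is.null(sp)) sp$min_identity else 0
  if (is.null(min_length)) min_length <- if (!is.null(sp)) sp$min_length else 0
  if (nrow(track) == 0L) return(track)
  if (min_identity > 0 && all(is.na(track$score))) {
    stop("identity filtering requested but track carries no scores",
         call. = FALSE)
  }
  pass_ident <- if (min_identity > 0) {
    !is.na(track$score) & track$score >= min_identity
  } else rep(TRUE, nrow(track))
  keep <- pass_ident & (track$end - track$start) >= min_length
  out <- track[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "label") <- attr(track, "label")
  attr(out, "species_pair") <- sp
  class(out) <- class(track)
  out
}

#' Build the gene x species-pair HCNE count matrix
#'
#' Counts HCNEs in each gene's locus window (`gene +/- flank`), normalizes
#' to counts per Mb, and takes `log2(normalized + pseudocount)`. The
#' normalization divisor is the full window length (gene length + 2 flank)
#' by default — the length bias the flanked window introduces grows with
#' gene length, so the window length is the quantity to divide out — with
#' bare gene length available as an option.
#'
#' @param genes a [gene_set()].
#' @param tracks named list of HCNE `feature_track`s, one per species pair.
#' @param flank locus window half-width in bp (default 2 Mb).
#' @param pseudocount added inside the log2 (default 1).
#' @param normalize `"window_length"` (default) or `"gene_length"`.
#' @return an `hcne_count_matrix`: list with `genes`, `pairs`, `raw`,
#'   `normalized`, `log2` matrices and the window parameters.
#' @export
build_count_matrix <- function(genes, tracks, flank = 2e6, pseudocount = 1,
                               normalize = c("window_length",
                                             "gene_length")) {
  normalize <- match.arg(normalize)
  pairs <- names(tracks)
  if (is.null(pairs)) pairs <- paste0("pair", seq_along(tracks))
  windows <- make_windows(genes, "locus", flank)
  raw <- sapply(tracks, function(tr) count_overlaps(windows, tr))
  raw <- matrix(as.numeric(raw), nrow = nrow(genes),
                dimnames = list(genes$gene_id, pairs))
  missing_chrom <- vapply(tracks, function(tr) {
    nrow(tr) > 0L && !all(unique(genes$chrom) %in% unique(tr$chrom))
  }, logical(1))
  if (any(missing_chrom)) {
    warning("gene chromosome absent from track(s): ",
            paste(pairs[missing_chrom], collapse = ", "),
            "; affected counts are 0", call. = FALSE)
  }
  glen <- genes$end - genes$start
  div_mb <- if (normalize == "window_length") (glen + 2 * flank) / 1e6 else
    glen / 1e6
  normalized <- raw / div_mb
  structure(list(genes = genes$gene_id, pairs = pairs, raw = raw,
                 normalized = normalized,
                 log2 = log2(normalized + pseudocount),
                 flank = flank, pseudocount = pseudocount,
                 normalize = normalize),
            class = "hcne_count_matrix")
}

#' Euclidean dissimilarity between genes' log2 HCNE profiles
#'
#' @param mat an `hcne_count_matrix` (or a plain numeric matrix of per-gene
#'   features).
#' @return symmetric gene x gene distance matrix with zero diagonal.
#' @export
hcne_dissimilarity <- function(mat) {
  m <- if (inherits(mat, "hcne_count_matrix")) mat$log2 else as.matrix(mat)
  d <- as.matrix(stats::dist(m, method = "euclidean"))
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Complete-linkage clustering of genes into HCNE classes
#'
#' Agglomerates with complete linkage and cuts the dendrogram into `k`
#' groups. With `k = 2`, cluster 1 is by convention the group with the
#' larger mean log2 HCNE value (the putative GRB targets).
#'
#' @param dissim symmetric distance matrix from [hcne_dissimilarity()].
#' @param mat the `hcne_count_matrix` used to orient labels (optional when
#'   `k != 2`; any per-gene numeric matrix also works).
#' @param k number of clusters (default 2).
#' @return an `hcne_clusters` list: `labels` (named integer vector),
#'   `hclust` (merge tree), `dissimilarity`, `k`, `cluster_means`.
#' @export
hcne_cluster <- function(dissim, mat = NULL, k = 2) {
  n <- nrow(dissim)
  if (k > n) stop("k = ", k, " exceeds the number of genes (", n, ")",
                  call. = FALSE)
  hc <- stats::hclust(stats::as.dist(dissim), method = "complete")
  labels <- stats::cutree(hc, k = k)
  means <- NULL
  if (!is.null(mat)) {
    m <- if (inherits(mat, "hcne_count_matrix")) mat$log2 else as.matrix(mat)
    means <- tapply(rowMeans(m)[names(labels)], labels, mean)
    # relabel so cluster 1 has the largest mean log2 value
    remap <- stats::setNames(seq_len(k), names(sort(means,
                                                    decreasing = TRUE)))
    labels <- stats::setNames(as.integer(remap[as.character(labels)]),
                              names(labels))
    means <- tapply(rowMeans(m)[names(labels)], labels, mean)
  }
  structure(list(labels = labels, hclust = hc, dissimilarity = dissim,
                 k = k, cluster_means = means),
            class = "hcne_clusters")
}

#' Cumulative positional profile of HCNEs around gene midpoints
#'
#' Pools, over a set of genes, the positions of element midpoints relative
#' to each gene's midpoint, bins them at `bin` bp over `+/- flank`, and
#' returns the cumulative fraction per bin (reaching 1 at the last bin
#' whenever any element falls in range).
#'
#' @param genes a [gene_set()] (typically one cluster's genes).
#' @param track an HCNE `feature_track`.
#' @param flank half-width of the profiled region (default 2 Mb).
#' @param bin bin width in bp (default 1 kb).
#' @return data.frame with `bin_start`, `bin_end` (positions relative to
#'   the gene midpoint), `count` and `cum_fraction`.
#' @export
cumulative_profile <- function(genes, track, flank = 2e6, bin = 1000) {
  breaks <- seq(-flank, flank, by = bin)
  nb <- length(breaks) - 1L
  counts <- numeric(nb)
  if (nrow(track) > 0L) {
    mids <- floor((track$start + track$end) / 2)
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      rel <- mids[track$chrom == g$chrom] - floor((g$start + g$end) / 2)
      rel <- rel[rel >= -flank & rel < flank]
      if (length(rel)) {
        counts <- counts + tabulate(findInterval(rel, breaks,
                                                 rightmost.closed = FALSE),
                                    nbins = nb)
      }
    }
  }
  total <- sum(counts)
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1L],
             count = counts,
             cum_fraction = if (total > 0) cumsum(counts) / total else
               numeric(nb))
}
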