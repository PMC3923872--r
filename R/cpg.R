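# CpG island accounting per gene, rank-sum comparison between clusters,
# and cumulative length distributions.

#' Summarize CpG island content per gene
#'
#' For each gene, islands "overlapping" the flanked locus
#' `[start - flank, end + flank)` by at least one base are counted;
#' `total_island_length` sums their full (unclipped) lengths, while
#' `cpg_bp_in_flank` is the number of bases of the flanked locus actually
#' covered (merged, clipped overlap), so
#' `cpg_bp_in_flank <= total_island_length` always.
#'
#' @param genes a [gene_set()].
#' @param cpg_track CpG island `feature_track`.
#' @param flank flank in bp around the gene locus (default 1 kb).
#' @return data.frame with `gene_id`, `n_islands`, `total_island_length`,
#'   `cpg_bp_in_flank`.
#' @export
summarize_cpg <- function(genes, cpg_track, flank = 1000) {
  windows <- make_windows(genes, "locus", flank)
  n_islands <- count_overlaps(windows, cpg_track)
  total_len <- numeric(nrow(genes))
  if (nrow(cpg_track) > 0L) {
    for (chr in unique(windows$chrom)) {
      wi <- which(windows$chrom == chr)
      ti <- which(cpg_track$chrom == chr)
      if (length(ti) == 0L) next
      hits <- IRanges::findOverlaps(
        as_iranges(windows$start[wi], windows$end[wi]),
        as_iranges(cpg_track$start[ti], cpg_track$end[ti]))
      if (length(hits) == 0L) next
      widths <- (cpg_track$end - cpg_track$start)[ti][
        S4Vectors::subjectHits(hits)]
      agg <- tapply(widths, S4Vectors::queryHits(hits), sum)
      total_len[wi[as.integer(names(agg))]] <- as.numeric(agg)
    }
  }
  data.frame(gene_id = genes$gene_id, n_islands = n_islands,
             total_island_length = total_len,
             cpg_bp_in_flank = overlap_bp(windows, cpg_track),
             stringsAsFactors = FALSE)
}

#' Two-sample rank-sum comparison of CpG island lengths
#'
#' Two-sided Wilcoxon–Mann–Whitney test with midranks for ties. When both
#' samples have at most 10 observations the p-value is computed by exact
#' enumeration of all assignments of the pooled ranks; otherwise the
#' tie-corrected normal approximation with continuity correction is used.
#' Genes without any island are excluded by the caller (comparing lengths
#' only makes sense among island-bearing genes).
#'
#' @param x,y numeric vectors of per-gene total island lengths.
#' @param method `"auto"` (default, exact when both n <= 10), or force
#'   `"exact"` / `"normal"`.
#' @return list with `statistic` (Mann–Whitney U for `x`), `p_value`, and
#'   `method`.
#' @export
compare_lengths <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both samples must be non-empty",
                                 call. = FALSE)
  N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  EW <- n1 * (N + 1) / 2
  if (method == "auto") {
    method <- if (n1 <= 10L && n2 <= 10L) "exact" else "normal"
  }
  if (method == "exact") {
    if (N > 24) stop("exact enumeration limited to n1 + n2 <= 24",
                     call. = FALSE)
    combos <- utils::combn(N, n1)
    Wall <- colSums(matrix(r[combos], nrow = n1))
    p <- mean(abs(Wall - EW) >= abs(W - EW) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) -
                                sum(ties^3 - ties) / (N * (N - 1)))
    z <- (abs(W - EW) - 0.5) / sqrt(sigma2)  # continuity-corrected
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal_tie_corrected"
  }
  list(statistic = U, p_value = p, method = method)
}

#' Empirical cumulative distribution of island lengths
#'
#' Standard right-continuous ECDF evaluated at the sorted unique lengths.
#'
#' @param lengths numeric vector.
#' @return data.frame with `length` and `fraction` (reaches 1 at the
#'   maximum), plus the `ecdf` function as an attribute.
#' @export
cumulative_length_curve <- function(lengths) {
  stopifnot(length(lengths) > 0)
  f <- stats::ecdf(lengths)
  xs <- sort(unique(lengths))
  out <- data.frame(length = xs, fraction = f(xs))
  attr(out, "ecdf") <- f
  out
}
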