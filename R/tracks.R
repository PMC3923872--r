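STRANDS <- c("+", "-", ".")

#' Construct a feature track
#'
#' A feature track is the package's container for sorted genomic intervals:
#' HCNEs, CpG islands, chromatin-state segments or ChIP tag positions.
#' Coordinates follow the BED convention throughout: 0-based, half-open
#' `[start, end)`.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-like vectors; `start >= 0`, `end > start`.
#' @param name optional labels (`NA` allowed).
#' @param score optional numeric score, e.g. percent identity for HCNEs.
#' @param strand one of `"+"`, `"-"`, `"."` per interval.
#' @param label track name attached as an attribute.
#' @param species_pair optional list describing an HCNE track's species pair:
#'   `name`, `min_identity` (percent) and `min_length` (bp).
#' @param extra optional data.frame of additional per-interval columns
#'   (e.g. peak p-values), recycled against the intervals.
#' @return a `feature_track`: a data.frame with columns `chrom`, `start`,
#'   `end`, `name`, `score`, `strand`, sorted by `(chrom, start, end)`.
#' @export
feature_track <- function(chrom = character(), start = numeric(),
                          end = numeric(), name = NA_character_,
                          score = NA_real_, strand = ".",
                          label = NULL, species_pair = NULL, extra = NULL) {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra) && n > 0L) {
    extra <- as.data.frame(extra, stringsAsFactors = FALSE)
    df <- cbind(df, extra[rep_len(seq_len(max(nrow(extra), 1L)), n), ,
                          drop = FALSE])
    rownames(df) <- NULL
  }
  validate_intervals(df)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "label") <- label
  attr(df, "species_pair") <- species_pair
  class(df) <- c("feature_track", "data.frame")
  df
}

validate_intervals <- function(df, where = "intervals") {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$start < 0)) {
    stop(where, ": negative start coordinate", call. = FALSE)
  }
  if (any(df$end <= df$start)) {
    stop(where, ": end must be greater than start", call. = FALSE)
  }
  bad <- !df$strand %in% STRANDS
  if (any(bad)) {
    stop(where, ": invalid strand value '", df$strand[which(bad)[1L]], "'",
         call. = FALSE)
  }
  invisible(df)
}

track_label <- function(track) attr(track, "label")

#' Read a BED3+ file into a feature track
#'
#' Accepts tab-delimited BED with 3 to 6 columns (chrom, start, end, and
#' optional name, score, strand). Lines are validated individually; a
#' malformed line raises an error naming its line number. The returned track
#' is sorted by `(chrom, start, end)` regardless of input order.
#'
#' @param path file path.
#' @param label optional track label.
#' @param species_pair optional species-pair descriptor (see
#'   [feature_track()]).
#' @return a `feature_track`.
#' @export
read_bed <- function(path, label = NULL, species_pair = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(feature_track(label = label, species_pair = species_pair))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    stop("malformed BED line ", which(nf < 3L)[1L], " in '", path,
         "': fewer than 3 fields", call. = FALSE)
  }
  get_col <- function(i, default) {
    vapply(parts, function(p) if (length(p) >= i) p[[i]] else default,
           character(1))
  }
  start <- suppressWarnings(as.numeric(get_col(2L, NA)))
  end <- suppressWarnings(as.numeric(get_col(3L, NA)))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad)) {
    stop("malformed BED line ", bad[1L], " in '", path,
         "': non-numeric coordinates", call. = FALSE)
  }
  bad <- which(end <= start | start < 0)
  if (length(bad)) {
    stop("invalid interval on BED line ", bad[1L], " in '", path,
         "': require 0 <= start < end", call. = FALSE)
  }
  name <- get_col(4L, NA_character_)
  name[name == "."] <- NA_character_
  score_chr <- get_col(5L, NA_character_)
  score <- suppressWarnings(as.numeric(score_chr))
  strand <- get_col(6L, ".")
  strand[is.na(strand) | !strand %in% STRANDS] <- "."
  feature_track(get_col(1L, NA), start, end, name, score, strand,
                label = label, species_pair = species_pair)
}

#' Write a feature track as BED
#'
#' Emits BED6 when any name/score/strand is informative, BED3 otherwise.
#' `read_bed()` composed with `write_bed()` is the identity on sorted tracks.
#'
#' @param track a `feature_track`.
#' @param path output path.
#' @export
write_bed <- function(track, path) {
  df <- as.data.frame(track)[, c("chrom", "start", "end", "name", "score",
                                 "strand")]
  use6 <- nrow(df) > 0L &&
    (any(!is.na(df$name)) || any(!is.na(df$score)) || any(df$strand != "."))
  if (use6) {
    df$name[is.na(df$name)] <- "."
    df$score <- ifelse(is.na(df$score), ".",
                       format(df$score, trim = TRUE, scientific = FALSE))
  } else {
    df <- df[, c("chrom", "start", "end"), drop = FALSE]
  }
  df$start <- format(df$start, trim = TRUE, scientific = FALSE)
  df$end <- format(df$end, trim = TRUE, scientific = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column chromosome-sizes table
#'
#' @param path tab-delimited file with columns name and length.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$length), df$chrom)
}

#' Construct a gene set
#'
#' The unit of every per-gene feature in the pipeline. The transcription
#' start site (TSS) is derived from strand: `start` for `+` genes, `end - 1`
#' for `-` genes (the last base of the half-open interval).
#'
#' @param gene_id unique stable identifiers.
#' @param chrom,start,end,strand locus coordinates (BED convention).
#' @param symbol display names; defaults to `gene_id`.
#' @return a `gene_set` data.frame with columns `gene_id`, `symbol`,
#'   `chrom`, `start`, `end`, `strand`, `tss`.
#' @export
gene_set <- function(gene_id, chrom, start, end, strand = "+",
                     symbol = gene_id) {
  n <- length(gene_id)
  df <- data.frame(
    gene_id = as.character(gene_id),
    symbol = rep_len(as.character(symbol), n),
    chrom = rep_len(as.character(chrom), n),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$gene_id)) {
    stop("gene_id values must be unique within a gene set", call. = FALSE)
  }
  if (any(!df$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'", call. = FALSE)
  }
  if (any(df$end <= df$start) || any(df$start < 0)) {
    stop("gene loci require 0 <= start < end", call. = FALSE)
  }
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  class(df) <- c("gene_set", "data.frame")
  df
}

#' Read genes from a BED6 file
#'
#' @param path BED6 file; the name column supplies `gene_id`.
#' @return a `gene_set`.
#' @export
read_genes <- function(path) {
  tr <- read_bed(path)
  if (nrow(tr) == 0L) stop("no gene records in '", path, "'", call. = FALSE)
  if (any(is.na(tr$name))) {
    stop("gene BED requires a name column (gene_id)", call. = FALSE)
  }
  strand <- tr$strand
  strand[strand == "."] <- "+"
  gene_set(tr$name, tr$chrom, tr$start, tr$end, strand)
}

#' Write a gene set as BED6
#' @param genes a `gene_set`.
#' @param path output path.
#' @export
write_genes <- function(genes, path) {
  write_bed(feature_track(genes$chrom, genes$start, genes$end,
                          name = genes$gene_id, score = 0,
                          strand = genes$strand), path)
}

#' Build anchored windows around gene loci
#'
#' Three anchor kinds are used by the pipeline: `"locus"` extends the whole
#' gene body by `flank` on both sides (the +/-2 Mb HCNE window), `"tss"`
#' centers on the transcription start site, and `"midpoint"` centers on
#' `floor((start + end) / 2)` (the transcription-elongation window).
#' Starts are clipped at 0; ends are clipped at the chromosome length only
#' when `chrom_sizes` is supplied.
#'
#' @param genes a `gene_set`.
#' @param anchor one of `"locus"`, `"tss"`, `"midpoint"`.
#' @param flank flank size in bp (>= 0; 0 gives the bare locus for the
#'   `"locus"` anchor).
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `anchor`, `strand`.
#' @export
make_windows <- function(genes, anchor = c("locus", "tss", "midpoint"),
                         flank, chrom_sizes = NULL) {
  anchor <- match.arg(anchor)
  stopifnot(is.numeric(flank), flank >= 0)
  if (anchor == "locus") {
    s <- genes$start - flank
    e <- genes$end + flank
  } else if (anchor == "tss") {
    s <- genes$tss - flank
    e <- genes$tss + flank
  } else {
    mid <- floor((genes$start + genes$end) / 2)
    s <- mid - flank
    e <- mid + flank
  }
  s <- pmax(s, 0)
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[genes$chrom]
    e <- ifelse(is.na(lim), e, pmin(e, lim))
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom, start = s,
             end = e, anchor = rep_len(anchor, nrow(genes)),
             strand = genes$strand, stringsAsFactors = FALSE)
}

# IRanges on 1-based closed coordinates; [start, end) maps to start+1 .. end.
as_iranges <- function(start, end) {
  IRanges::IRanges(start = as.integer(start + 1), end = as.integer(end))
}

#' Count track intervals overlapping each window
#'
#' An interval counts when it shares at least one base with the half-open
#' window; an interval abutting the boundary does not. Chromosomes absent
#' from the track yield 0.
#'
#' @param windows data.frame from [make_windows()] (or any frame with
#'   `chrom`, `start`, `end`).
#' @param track a `feature_track`.
#' @return integer vector, one count per window row.
#' @export
count_overlaps <- function(windows, track) {
  out <- integer(nrow(windows))
  if (nrow(track) == 0L || nrow(windows) == 0L) return(out)
  for (chr in unique(windows$chrom)) {
    wi <- which(windows$chrom == chr)
    ti <- which(track$chrom == chr)
    if (length(ti) == 0L) next
    q <- as_iranges(windows$start[wi], windows$end[wi])
    s <- as_iranges(track$start[ti], track$end[ti])
    out[wi] <- IRanges::countOverlaps(q, s)
  }
  out
}

#' Base pairs of each window covered by a track
#'
#' Overlapping intervals within the track are merged before summation, so
#' the result is the number of distinct window bases covered.
#'
#' @inheritParams count_overlaps
#' @return numeric vector of covered bp per window row.
#' @export
overlap_bp <- function(windows, track) {
  out <- numeric(nrow(windows))
  if (nrow(track) == 0L || nrow(windows) == 0L) return(out)
  for (chr in unique(windows$chrom)) {
    wi <- which(windows$chrom == chr)
    ti <- which(track$chrom == chr)
    if (length(ti) == 0L) next
    q <- as_iranges(windows$start[wi], windows$end[wi])
    s <- IRanges::reduce(as_iranges(track$start[ti], track$end[ti]))
    hits <- IRanges::findOverlaps(q, s)
    if (length(hits) == 0L) next
    qh <- S4Vectors::queryHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      q[qh], s[S4Vectors::subjectHits(hits)]))
    agg <- tapply(ov, qh, sum)
    out[wi[as.integer(names(agg))]] <- as.numeric(agg)
  }
  out
}

#' Merge overlapping intervals of a track
#' @param track a `feature_track`.
#' @return a `feature_track` of disjoint merged intervals (name/score/strand
#'   dropped).
#' @export
merge_track <- function(track) {
  if (nrow(track) == 0L) return(feature_track(label = track_label(track)))
  pieces <- lapply(split(seq_len(nrow(track)), track$chrom), function(idx) {
    r <- IRanges::reduce(as_iranges(track$start[idx], track$end[idx]))
    data.frame(chrom = track$chrom[idx[1L]],
               start = IRanges::start(r) - 1,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  feature_track(df$chrom, df$start, df$end, label = track_label(track))
}
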