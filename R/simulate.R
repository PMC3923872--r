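# Seeded toy-genome generator. Every sub-generator draws from its own RNG
# substream derived from the master seed by a labelled hash, so adding or
# re-running one generator never perturbs the others.

#' Configuration for the synthetic genome
#'
#' The defaults define the study conditions used throughout the test suite:
#' 60 genes on one chromosome, half of them planted as GRB targets; five
#' species pairs whose HCNE density decays with evolutionary distance
#' (target windows expect 80 elements for the closest pair, background
#' windows 8); long multi-island CpG content over targets (3000 bp) versus a
#' short promoter island over non-targets (300 bp); five cell lines with one
#' flagged as the stem line; and 50,000 tags per histone mark and cell line.
#'
#' @param seed master RNG seed (integer).
#' @param n_genes number of genes.
#' @param frac_target fraction of genes planted as targets, in (0, 1).
#'   The target count is `floor(n_genes * frac_target + 0.5)` (ties round
#'   toward targets).
#' @param chrom chromosome name of the toy genome.
#' @param chrom_length chromosome length in bp; by default sized so that
#'   the +/-2 Mb windows of distinct genes are disjoint.
#' @param species_pairs data.frame with columns `name`, `decay` (in (0, 1],
#'   non-increasing with evolutionary distance), `min_identity` (percent)
#'   and `min_length` (bp) — the per-pair HCNE cutoffs.
#' @param hcne_rate_target,hcne_rate_background expected HCNE counts per
#'   +/-2 Mb window at decay 1 (>= 0).
#' @param cpg_len_target,cpg_len_background mean total CpG island length
#'   (bp) per gene; 0 disables islands for that class.
#' @param cell_lines character vector of cell line names.
#' @param stem_cell_line which cell line is the embryonic-stem-like line
#'   (bivalent promoters are planted there).
#' @param reads_per_mark tags per (mark, cell line) library.
#' @param rpkm_threshold expression call threshold (default 0.3).
#' @param fragment_size ChIP fragment extension length in bp.
#' @param flank half-width of the gene-locus window (default 2 Mb).
#' @param gene_length_range min/max gene length in bp.
#' @param locus_sharing if `TRUE`, `n_shared_pairs` pairs of target genes
#'   are placed < 2 Mb apart so their locus windows overlap, exercising
#'   multi-target GRB resolution.
#' @param n_shared_pairs number of shared-locus target pairs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 60L,
                       frac_target = 0.5,
                       chrom = "chrS",
                       chrom_length = NULL,
                       species_pairs = default_species_pairs(),
                       hcne_rate_target = 80,
                       hcne_rate_background = 8,
                       cpg_len_target = 3000,
                       cpg_len_background = 300,
                       cell_lines = c("Gm12878", "H1hesc", "Huvec",
                                      "HepG2", "K562"),
                       stem_cell_line = "H1hesc",
                       reads_per_mark = 50000L,
                       rpkm_threshold = 0.3,
                       fragment_size = 200L,
                       flank = 2e6,
                       gene_length_range = c(2e4, 1.5e5),
                       locus_sharing = FALSE,
                       n_shared_pairs = 2L) {
  stopifnot(frac_target > 0, frac_target < 1, n_genes >= 2,
            hcne_rate_target >= 0, hcne_rate_background >= 0,
            cpg_len_target >= 0, cpg_len_background >= 0,
            reads_per_mark >= 0, fragment_size > 0, flank > 0)
  species_pairs <- as.data.frame(species_pairs, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "decay", "min_identity", "min_length") %in%
                  names(species_pairs)))
  if (any(species_pairs$decay <= 0) || any(species_pairs$decay > 1) ||
      is.unsorted(rev(species_pairs$decay))) {
    stop("species pair decay factors must lie in (0, 1] and be ",
         "non-increasing with evolutionary distance", call. = FALSE)
  }
  if (!stem_cell_line %in% cell_lines) {
    stop("stem_cell_line must be one of cell_lines", call. = FALSE)
  }
  slot <- 2 * flank + max(gene_length_range) + 5e5
  needed <- n_genes * slot + 2 * flank
  if (is.null(chrom_length)) chrom_length <- needed
  if (chrom_length < needed) {
    stop("chrom_length ", chrom_length, " too small for ", n_genes,
         " genes spaced ", slot, " bp apart (need >= ", needed, ")",
         call. = FALSE)
  }
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              frac_target = frac_target, chrom = chrom,
              chrom_length = chrom_length, species_pairs = species_pairs,
              hcne_rate_target = hcne_rate_target,
              hcne_rate_background = hcne_rate_background,
              cpg_len_target = cpg_len_target,
              cpg_len_background = cpg_len_background,
              cell_lines = cell_lines, stem_cell_line = stem_cell_line,
              reads_per_mark = as.integer(reads_per_mark),
              rpkm_threshold = rpkm_threshold,
              fragment_size = as.integer(fragment_size), flank = flank,
              gene_length_range = gene_length_range,
              locus_sharing = isTRUE(locus_sharing),
              n_shared_pairs = as.integer(n_shared_pairs),
              slot = slot)
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_species_pairs <- function() {
  data.frame(
    name = c("mouse", "chicken", "xenopus", "fugu", "zebrafish"),
    decay = c(1, 0.55, 0.4, 0.3, 0.2),
    min_identity = c(70, 80, 85, 90, 95),
    min_length = rep(50, 5),
    stringsAsFactors = FALSE
  )
}

#' Derive a labelled RNG substream seed
#'
#' Deterministic 31-bit hash of `(seed, label)` used to give each
#' sub-generator an independent, reproducible stream.
#'
#' @param seed master seed.
#' @param label stream label.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, label) {
  m <- 2147483563
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% m
  as.integer((h + (as.numeric(seed) %% m) * 48271) %% m)
}

with_substream <- function(cfg, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(cfg$seed, label))
  force(expr)
}

#' Simulate gene loci and ground truth
#'
#' Genes are placed in disjoint slots along one chromosome so their
#' +/-2 Mb locus windows do not overlap; with `locus_sharing` enabled,
#' designated pairs of target genes are instead placed < 2 Mb apart.
#' The ground truth records, per gene, target status, a per-cell-line
#' expression plan, and whether the gene is planted bivalent in the stem
#' line (a target not expressed there).
#'
#' @param cfg a [sim_config()].
#' @return list with elements `genes` (a [gene_set()]) and `truth` (list
#'   with data.frame `genes` — `gene_id`, `is_target`, `bivalent_in_stem` —
#'   and logical matrix `expressed`, gene x cell line).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_substream(cfg, "genome", {
    n <- cfg$n_genes
    n_target <- as.integer(floor(n * cfg$frac_target + 0.5))
    is_target <- rep(FALSE, n)
    is_target[sample.int(n, n_target)] <- TRUE

    len <- round(stats::runif(n, cfg$gene_length_range[1],
                              cfg$gene_length_range[2]))
    jitter <- round(stats::runif(n, 0, 2e5))
    start <- cfg$flank + (seq_len(n) - 1) * cfg$slot + jitter

    if (cfg$locus_sharing) {
      tidx <- which(is_target)
      n_pairs <- min(cfg$n_shared_pairs, floor(length(tidx) / 2))
      for (p in seq_len(n_pairs)) {
        a <- tidx[2 * p - 1]
        b <- tidx[2 * p]
        # place b just downstream of a: windows overlap, loci do not
        start[b] <- start[a] + len[a] + round(stats::runif(1, 6e5, 1.4e6))
      }
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    ids <- sprintf("G%03d", seq_len(n))
    genes <- gene_set(ids, cfg$chrom, start, start + len, strand)

    ncl <- length(cfg$cell_lines)
    p_expr <- matrix(0.65, n, ncl, dimnames = list(ids, cfg$cell_lines))
    p_expr[is_target, ] <- 0.4
    p_expr[is_target, cfg$stem_cell_line] <- 0.5
    expressed <- matrix(stats::runif(n * ncl), n, ncl,
                        dimnames = dimnames(p_expr)) < p_expr
    bivalent <- is_target & !expressed[, cfg$stem_cell_line]
    truth <- list(
      genes = data.frame(gene_id = ids, is_target = is_target,
                         bivalent_in_stem = bivalent,
                         stringsAsFactors = FALSE),
      expressed = expressed
    )
    list(genes = genes, truth = truth)
  })
}

locus_window <- function(gene, flank) {
  c(max(gene$start - flank, 0), gene$end + flank)
}

#' Simulate per-species-pair HCNE tracks
#'
#' For a pair with decay `d`, each target gene receives
#' `Poisson(d * hcne_rate_target)` elements in its locus window and each
#' background gene `Poisson(d * hcne_rate_background)`; 80% of positions
#' are drawn from a normal centred on the gene midpoint (sd 400 kb), the
#' rest uniformly over the window. Element lengths exceed the pair's length
#' cutoff and percent identities lie above its identity cutoff.
#'
#' @param genes,truth from [simulate_genome()].
#' @param cfg a [sim_config()].
#' @return named list of `feature_track`s, one per species pair.
#' @export
simulate_hcnes <- function(genes, truth, cfg) {
  with_substream(cfg, "hcne", {
    is_target <- truth$genes$is_target
    out <- list()
    for (j in seq_len(nrow(cfg$species_pairs))) {
      pair <- cfg$species_pairs[j, ]
      rows <- vector("list", nrow(genes))
      for (i in seq_len(nrow(genes))) {
        g <- genes[i, ]
        rate <- pair$decay * if (is_target[i]) cfg$hcne_rate_target else
          cfg$hcne_rate_background
        k <- if (rate > 0) stats::rpois(1, rate) else 0L
        if (k == 0L) next
        w <- locus_window(g, cfg$flank)
        gmid <- floor((g$start + g$end) / 2)
        near <- stats::runif(k) < 0.8
        pos <- ifelse(near, stats::rnorm(k, gmid, 4e5),
                      stats::runif(k, w[1], w[2]))
        len <- round(pair$min_length + stats::rexp(k, 1 / 150))
        s <- pmin(pmax(round(pos - len / 2), w[1]), w[2] - len - 1)
        s <- pmax(s, 0)
        rows[[i]] <- data.frame(
          chrom = g$chrom, start = s, end = s + len,
          name = sprintf("%s_%s_%d", pair$name, g$gene_id, seq_len(k)),
          score = stats::runif(k, pair$min_identity, 100),
          stringsAsFactors = FALSE
        )
      }
      df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
      if (is.null(df)) df <- data.frame(chrom = character(),
                                        start = numeric(), end = numeric(),
                                        name = character(),
                                        score = numeric())
      out[[pair$name]] <- feature_track(
        df$chrom, df$start, df$end, df$name, df$score,
        label = paste0("hcne_", pair$name),
        species_pair = list(name = pair$name,
                            min_identity = pair$min_identity,
                            min_length = pair$min_length))
    }
    out
  })
}

#' Simulate a CpG island track
#'
#' Target genes receive 1–3 islands whose total length is drawn around
#' `cpg_len_target`, the first overlapping the promoter and the rest placed
#' in the gene body; non-target genes receive at most one short promoter
#' island around `cpg_len_background`. Islands never extend beyond
#' `gene end + 1 kb` (nor more than 1 kb upstream of the gene).
#'
#' @inheritParams simulate_hcnes
#' @return a `feature_track` of CpG islands.
#' @export
simulate_cpg <- function(genes, truth, cfg) {
  with_substream(cfg, "cpg", {
    rows <- list()
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      lo <- max(g$start - 1000, 0)
      hi <- g$end + 1000
      if (truth$genes$is_target[i]) {
        if (cfg$cpg_len_target <= 0) next
        k <- sample(1:3, 1)
        total <- max(200 * k,
                     round(stats::rnorm(1, cfg$cpg_len_target,
                                        0.15 * cfg$cpg_len_target)))
        wts <- stats::runif(k, 0.5, 1.5)
        lens <- pmax(150, round(total * wts / sum(wts)))
        # first island straddles the TSS, the rest sit in the gene body
        s1 <- g$tss - round(0.3 * lens[1])
        starts <- s1
        if (k > 1) {
          body <- stats::runif(k - 1, 0.2, 0.9)
          starts <- c(s1, round(g$start + body * (g$end - g$start)))
        }
        for (q in seq_len(k)) {
          s <- min(max(starts[q], lo), hi - lens[q])
          s <- max(s, 0)
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = g$chrom, start = s, end = min(s + lens[q], hi),
            name = sprintf("cpg_%s_%d", g$gene_id, q),
            stringsAsFactors = FALSE)
        }
      } else {
        if (cfg$cpg_len_background <= 0 || stats::runif(1) > 0.7) next
        len <- max(100, round(stats::rnorm(1, cfg$cpg_len_background,
                                           0.2 * cfg$cpg_len_background)))
        s <- max(g$tss - round(len / 2), 0)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = g$chrom, start = s, end = min(s + len, hi),
          name = sprintf("cpg_%s_1", g$gene_id), stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    if (is.null(df)) {
      return(feature_track(label = "cpg"))
    }
    feature_track(df$chrom, df$start, df$end, df$name, label = "cpg")
  })
}

#' Simulate ChIP tag libraries
#'
#' Tag 5' positions are sampled per mark with the mark's canonical
#' semantics: H3K4me3 around TSSs of genes expressed in the cell line
#' (Normal(tss, 500)); H3K36me3 uniformly over expressed gene bodies;
#' H3K4me1 around HCNE midpoints (Normal(mid, 300)) with a 10% genome-wide
#' uniform background; H3K27me3 around TSSs of target genes not expressed
#' in the cell line (Normal(tss, 2 kb)) — in the stem line these are exactly
#' the planted bivalent promoters. Tags are 1 bp intervals carrying strand;
#' fragment extension is a downstream concern.
#'
#' @inheritParams simulate_hcnes
#' @param hcnes output of [simulate_hcnes()]; the closest pair's track
#'   anchors the enhancer mark.
#' @return named list of [tag_library()] objects keyed `"mark:cell_line"`.
#' @export
simulate_reads <- function(genes, truth, cfg, hcnes) {
  with_substream(cfg, "reads", {
    n_tags <- cfg$reads_per_mark
    is_target <- truth$genes$is_target
    enh <- hcnes[[1L]]
    out <- list()
    draw <- function(pos) {
      pos <- pmin(pmax(round(pos), 0), cfg$chrom_length - 1)
      feature_track(rep(cfg$chrom, length(pos)), pos, pos + 1,
                    strand = sample(c("+", "-"), length(pos),
                                    replace = TRUE))
    }
    for (cl in cfg$cell_lines) {
      expr <- truth$expressed[, cl]
      for (mark in c("H3K4me3", "H3K36me3", "H3K4me1", "H3K27me3")) {
        if (n_tags == 0L) {
          tr <- feature_track()
        } else if (mark == "H3K4me3") {
          idx <- which(expr)
          tr <- if (length(idx) == 0L) feature_track() else {
            gi <- sample(idx, n_tags, replace = TRUE)
            draw(stats::rnorm(n_tags, genes$tss[gi], 500))
          }
        } else if (mark == "H3K36me3") {
          idx <- which(expr)
          tr <- if (length(idx) == 0L) feature_track() else {
            gi <- sample(idx, n_tags, replace = TRUE)
            draw(stats::runif(n_tags, genes$start[gi], genes$end[gi]))
          }
        } else if (mark == "H3K4me1") {
          bg <- stats::runif(n_tags) < 0.1
          pos <- stats::runif(n_tags, 0, cfg$chrom_length)
          if (nrow(enh) > 0L && any(!bg)) {
            ei <- sample.int(nrow(enh), sum(!bg), replace = TRUE)
            mid <- floor((enh$start[ei] + enh$end[ei]) / 2)
            pos[!bg] <- stats::rnorm(sum(!bg), mid, 300)
          }
          tr <- draw(pos)
        } else {
          idx <- which(is_target & !expr)
          tr <- if (length(idx) == 0L) {
            draw(stats::runif(n_tags, 0, cfg$chrom_length))
          } else {
            gi <- sample(rep(idx, 2), n_tags, replace = TRUE)
            draw(stats::rnorm(n_tags, genes$tss[gi], 2000))
          }
        }
        out[[paste(mark, cl, sep = ":")]] <-
          tag_library(tr, mark = mark, cell_line = cl,
                      fragment_size = cfg$fragment_size)
      }
    }
    out
  })
}

#' Simulate an RPKM expression table
#'
#' Entries planned as expressed draw from a log-normal with median ~30
#' (well above the 0.3 call threshold); entries planned as silent draw
#' below 0.3, including exact zeros.
#'
#' @inheritParams simulate_hcnes
#' @return data.frame with `gene_id` and one numeric column per cell line.
#' @export
simulate_expression <- function(genes, truth, cfg) {
  with_substream(cfg, "expression", {
    n <- nrow(genes)
    ncl <- length(cfg$cell_lines)
    vals <- matrix(0, n, ncl, dimnames = list(genes$gene_id, cfg$cell_lines))
    on <- truth$expressed
    vals[on] <- pmax(stats::rlnorm(sum(on), log(30), 1), 0.5)
    off <- !on
    u <- stats::runif(sum(off))
    vals[off] <- ifelse(u < 0.3, 0, stats::runif(sum(off), 0, 0.25))
    data.frame(gene_id = genes$gene_id, vals, row.names = NULL,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
}

SIM_STATES <- c("Active_Promoter", "Poised_Promoter", "Polycomb_Repressed",
                "Txn_Elongation", "Poised_Enhancer", "Weak_Enhancer",
                "Heterochrom_Low")

#' Simulate a chromatin-state segmentation for the stem cell line
#'
#' Deterministic given the planted features (no RNG): genes expressed in
#' the stem line get an Active_Promoter segment over the TSS and a
#' Txn_Elongation segment over the proximal gene body; every target gene
#' gets a Poised_Promoter segment and an enhancer neighbourhood
#' (Poised_Enhancer plus Weak_Enhancer segments) mirroring its HCNE
#' content; planted bivalent genes additionally get a Polycomb_Repressed
#' domain. Remaining bases are Heterochrom_Low. Segments tile the
#' chromosome without gaps or overlaps.
#'
#' @inheritParams simulate_hcnes
#' @return a `feature_track` whose `name` column carries state labels.
#' @export
simulate_states <- function(genes, truth, cfg) {
  expr <- truth$expressed[, cfg$stem_cell_line]
  is_target <- truth$genes$is_target
  bivalent <- truth$genes$bivalent_in_stem
  kb <- 1000
  feats <- list()
  add <- function(tss, dir, a, b, state, priority) {
    lo <- tss + dir * a
    hi <- tss + dir * b
    s <- min(lo, hi); e <- max(lo, hi)
    s <- max(s, 0); e <- min(e, cfg$chrom_length)
    if (e > s) feats[[length(feats) + 1L]] <<-
      data.frame(start = s, end = e, state = state, priority = priority,
                 stringsAsFactors = FALSE)
  }
  weak_offsets <- list(c(-5.5, -4.5), c(-7, -6), c(-8.5, -7.5), c(-10, -9),
                       c(15, 16), c(30, 31), c(60, 61), c(-30, -29),
                       c(-60, -59))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    dir <- if (g$strand == "+") 1 else -1
    body <- g$end - g$start
    if (expr[i]) {
      add(g$tss, dir, -1 * kb, 1 * kb, "Active_Promoter", 6)
      add(g$tss, dir, 1 * kb, (1 + min(5, body / kb)) * kb,
          "Txn_Elongation", 3)
    }
    if (is_target[i]) {
      add(g$tss, dir, -2 * kb, -1 * kb, "Poised_Promoter", 5)
      add(g$tss, dir, -4 * kb, -2 * kb, "Poised_Enhancer", 2)
      for (off in weak_offsets) {
        add(g$tss, dir, off[1] * kb, off[2] * kb, "Weak_Enhancer", 1)
      }
    }
    if (bivalent[i]) {
      add(g$tss, dir, 1 * kb, 4 * kb, "Polycomb_Repressed", 4)
    }
  }
  fd <- if (length(feats)) do.call(rbind, feats) else
    data.frame(start = numeric(), end = numeric(), state = character(),
               priority = numeric())
  pts <- sort(unique(c(0, cfg$chrom_length, fd$start, fd$end)))
  seg_s <- pts[-length(pts)]
  seg_e <- pts[-1L]
  lab <- rep("Heterochrom_Low", length(seg_s))
  if (nrow(fd) > 0L) {
    hits <- IRanges::findOverlaps(as_iranges(seg_s, seg_e),
                                  as_iranges(fd$start, fd$end))
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    if (length(qh)) {
      ord <- order(qh, -fd$priority[sh])
      keep <- !duplicated(qh[ord])
      lab[qh[ord][keep]] <- fd$state[sh[ord][keep]]
    }
  }
  # merge adjacent same-state runs
  runs <- rle(lab)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  feature_track(rep(cfg$chrom, length(runs$values)),
                seg_s[starts], seg_e[ends], name = runs$values,
                label = "chromatin_states")
}

#' Run every generator and optionally write all tracks to disk
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory; when given, genes (BED6), per-pair
#'   HCNE BED, CpG BED, per-(mark, cell line) tag BED, the RPKM table, the
#'   state segmentation BED4, the ground-truth table and a manifest listing
#'   all paths with the seed and md5 checksums are written there.
#' @return list with `genes`, `truth`, `hcnes`, `cpg`, `reads`, `rpkm`,
#'   `states`, `config` (and `manifest` when `dir` is given).
#' @export
simulate_grb_data <- function(cfg = sim_config(), dir = NULL) {
  gen <- simulate_genome(cfg)
  hcnes <- simulate_hcnes(gen$genes, gen$truth, cfg)
  cpg <- simulate_cpg(gen$genes, gen$truth, cfg)
  reads <- simulate_reads(gen$genes, gen$truth, cfg, hcnes)
  rpkm <- simulate_expression(gen$genes, gen$truth, cfg)
  states <- simulate_states(gen$genes, gen$truth, cfg)
  res <- list(genes = gen$genes, truth = gen$truth, hcnes = hcnes,
              cpg = cpg, reads = reads, rpkm = rpkm, states = states,
              config = cfg)
  if (!is.null(dir)) {
    res$manifest <- write_sim_data(res, dir)
  }
  res
}

write_tsv_commented <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_sim_data <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genes = file.path(dir, "genes.bed"))
  write_genes(sim$genes, paths[["genes"]])
  for (pair in names(sim$hcnes)) {
    p <- file.path(dir, sprintf("hcne_%s.bed", pair))
    write_bed(sim$hcnes[[pair]], p)
    paths[[paste0("hcne_", pair)]] <- p
  }
  paths[["cpg"]] <- file.path(dir, "cpg.bed")
  write_bed(sim$cpg, paths[["cpg"]])
  for (key in names(sim$reads)) {
    fname <- sprintf("tags_%s.bed", gsub(":", "_", key))
    p <- file.path(dir, fname)
    write_bed(sim$reads[[key]]$tags, p)
    paths[[paste0("tags_", gsub(":", "_", key))]] <- p
  }
  paths[["rpkm"]] <- file.path(dir, "rpkm.tsv")
  write_tsv_commented(sim$rpkm, paths[["rpkm"]],
                      "RPKM per gene and cell line (synthetic)")
  paths[["states"]] <- file.path(dir, "states.bed")
  st <- sim$states
  utils::write.table(
    data.frame(st$chrom, format(st$start, scientific = FALSE, trim = TRUE),
               format(st$end, scientific = FALSE, trim = TRUE), st$name),
    paths[["states"]], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  paths[["truth"]] <- file.path(dir, "truth.tsv")
  truth_df <- cbind(sim$truth$genes,
                    stats::setNames(as.data.frame(sim$truth$expressed),
                                    paste0("expressed_",
                                           colnames(sim$truth$expressed))))
  write_tsv_commented(truth_df, paths[["truth"]],
                      "planted ground truth (synthetic)")
  manifest <- data.frame(
    name = names(paths), path = unname(paths),
    md5 = unname(tools::md5sum(unname(paths))),
    stringsAsFactors = FALSE)
  write_tsv_commented(manifest, file.path(dir, "MANIFEST.tsv"),
                      c(paste("seed:", sim$config$seed),
                        paste("n_genes:", sim$config$n_genes)))
  manifest
}
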