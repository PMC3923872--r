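# Brute-force oracles and tiny fixture builders shared across test files.
# Oracles deliberately avoid the package's interval machinery: they work
# per base or per pair, so they stay independent of the code they check.

# all-pairs overlap count for one half-open window
brute_count <- function(wchrom, wstart, wend, track) {
  sum(track$chrom == wchrom & track$start < wend & track$end > wstart)
}

# per-base coverage membership for one window
brute_overlap_bp <- function(wchrom, wstart, wend, track) {
  if (wend <= wstart) return(0)
  bases <- rep(FALSE, wend - wstart)
  for (i in seq_len(nrow(track))) {
    if (track$chrom[i] != wchrom) next
    s <- max(track$start[i], wstart)
    e <- min(track$end[i], wend)
    if (e > s) bases[(s - wstart + 1):(e - wstart)] <- TRUE
  }
  sum(bases)
}

random_track <- function(n, chrom = "chr1", span = 10000, max_len = 500) {
  s <- sort(sample.int(span, n, replace = TRUE)) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  feature_track(rep(chrom, n), s, s + len)
}

tiny_genes <- function() {
  gene_set(c("gA", "gB", "gC"),
           chrom = "chr1",
           start = c(10000, 60000, 120000),
           end = c(20000, 80000, 130000),
           strand = c("+", "-", "+"))
}

# small-but-complete simulation shared by several files (cached per run)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42L, n_genes = 20L, reads_per_mark = 20000L)
      cache <<- simulate_grb_data(cfg)
    }
    cache
  }
})
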