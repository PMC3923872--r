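test_that("simulate_genome rounds target counts and is deterministic", {
  cfg <- sim_config(seed = 5L, n_genes = 2L, frac_target = 0.5)
  gen <- simulate_genome(cfg)
  expect_equal(sum(gen$truth$genes$is_target), 1L)

  gen2 <- simulate_genome(cfg)
  expect_identical(gen, gen2)

  full <- simulate_grb_data(sim_config(seed = 9L, n_genes = 10L,
                                       reads_per_mark = 5000L))
  full2 <- simulate_grb_data(sim_config(seed = 9L, n_genes = 10L,
                                        reads_per_mark = 5000L))
  expect_identical(full[setdiff(names(full), "config")],
                   full2[setdiff(names(full2), "config")])
})

test_that("gene spacing keeps locus windows disjoint by default", {
  sim <- small_sim()
  w <- make_windows(sim$genes, "locus", sim$config$flank)
  w <- w[order(w$start), ]
  expect_true(all(w$start[-1] >= w$end[-nrow(w)]))
})

test_that("locus sharing places target pairs with overlapping windows", {
  cfg <- sim_config(seed = 3L, n_genes = 16L, locus_sharing = TRUE,
                    n_shared_pairs = 2L)
  gen <- simulate_genome(cfg)
  w <- make_windows(gen$genes, "locus", cfg$flank)
  w <- w[order(w$start), ]
  n_overlapping <- sum(w$start[-1] < w$end[-nrow(w)])
  expect_gte(n_overlapping, 1L)
  # genes themselves never overlap
  g <- gen$genes[order(gen$genes$start), ]
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
})

test_that("chromosome too small for the requested spacing errors", {
  expect_error(sim_config(n_genes = 60L, chrom_length = 1e7), "too small")
})

test_that("HCNE generator respects rates, decay, and window bounds", {
  cfg0 <- sim_config(seed = 21L, n_genes = 12L, hcne_rate_background = 0)
  gen <- simulate_genome(cfg0)
  hc <- simulate_hcnes(gen$genes, gen$truth, cfg0)
  bg <- gen$genes[!gen$truth$genes$is_target, , drop = FALSE]
  wbg <- make_windows(bg, "locus", cfg0$flank)
  expect_true(all(count_overlaps(wbg, hc$mouse) == 0))

  # every element inside its gene's locus window (all targets here)
  sim <- small_sim()
  w <- make_windows(sim$genes, "locus", sim$config$flank)
  for (pair in names(sim$hcnes)) {
    tr <- sim$hcnes[[pair]]
    inside <- vapply(seq_len(nrow(tr)), function(i) {
      any(w$start <= tr$start[i] & tr$end[i] <= w$end)
    }, logical(1))
    expect_true(all(inside))
    sp <- attr(tr, "species_pair")
    expect_true(all(tr$end - tr$start >= sp$min_length))
    expect_true(all(tr$score >= sp$min_identity))
  }
})

test_that("HCNE counts scale with the decay factor as Poisson means", {
  cfg <- sim_config(seed = 31L, n_genes = 60L,
                    species_pairs = data.frame(
                      name = c("near", "far"), decay = c(1, 0.2),
                      min_identity = c(70, 90), min_length = 50),
                    hcne_rate_target = 80, hcne_rate_background = 80)
  gen <- simulate_genome(cfg)
  hc <- simulate_hcnes(gen$genes, gen$truth, cfg)
  w <- make_windows(gen$genes, "locus", cfg$flank)
  near <- count_overlaps(w, hc$near)
  far <- count_overlaps(w, hc$far)
  # ratio of Poisson means is 5; allow 3 standard errors on the ratio
  se <- sqrt(mean(near) / length(near)) / mean(far) +
    mean(near) * sqrt(mean(far) / length(far)) / mean(far)^2
  expect_lt(abs(mean(near) / mean(far) - 5), 3 * max(se, 0.3))
})

test_that("CpG generator separates classes and respects gene bounds", {
  sim <- small_sim()
  cfg <- sim$config
  cpg <- sim$cpg
  genes <- sim$genes
  summ <- summarize_cpg(genes, cpg, flank = 1000)
  is_t <- sim$truth$genes$is_target
  expect_gt(mean(summ$total_island_length[is_t]),
            mean(summ$total_island_length[!is_t]))
  # islands stay within [gene.start - 1 kb, gene.end + 1 kb]
  for (i in seq_len(nrow(cpg))) {
    gid <- sub("^cpg_(G\\d+)_.*$", "\\1", cpg$name[i])
    g <- genes[genes$gene_id == gid, ]
    expect_lte(cpg$end[i], g$end + 1000)
    expect_gte(cpg$start[i], max(g$start - 1000, 0))
  }

  cfg0 <- sim_config(seed = 8L, n_genes = 10L, cpg_len_background = 0)
  gen <- simulate_genome(cfg0)
  cpg0 <- simulate_cpg(gen$genes, gen$truth, cfg0)
  bg <- gen$genes[!gen$truth$genes$is_target, , drop = FALSE]
  expect_true(all(summarize_cpg(bg, cpg0)$n_islands == 0))
})

test_that("planted CpG length difference is detected by the rank-sum test", {
  sim <- small_sim()
  summ <- summarize_cpg(sim$genes, sim$cpg)
  is_t <- sim$truth$genes$is_target
  keep <- summ$n_islands > 0
  res <- compare_lengths(summ$total_island_length[is_t & keep],
                         summ$total_island_length[!is_t & keep])
  expect_lt(res$p_value, 0.01)
})

test_that("read generator places marks with the planted semantics", {
  sim <- small_sim()
  cfg <- sim$config
  stem <- cfg$stem_cell_line
  truth <- sim$truth

  # H3K4me3 concentrates at TSSs of expressed genes
  k4 <- sim$reads[[paste0("H3K4me3:", stem)]]
  expr_idx <- which(truth$expressed[, stem])
  wtss <- make_windows(sim$genes[expr_idx, , drop = FALSE], "tss", 2000)
  expect_gt(sum(count_overlaps(wtss, k4$tags)) / k4$library_size, 0.9)

  # planted bivalent gene: K27me3 within +/-10 kb of its TSS
  k27 <- sim$reads[[paste0("H3K27me3:", stem)]]
  biv <- sim$genes[truth$genes$bivalent_in_stem, , drop = FALSE]
  expect_gt(nrow(biv), 0)
  wbiv <- make_windows(biv, "tss", 10000)
  expect_true(all(count_overlaps(wbiv, k27$tags) > 0))

  # empty library when reads_per_mark = 0
  cfg0 <- sim_config(seed = 2L, n_genes = 6L, reads_per_mark = 0L)
  gen0 <- simulate_genome(cfg0)
  r0 <- simulate_reads(gen0$genes, gen0$truth, cfg0,
                       simulate_hcnes(gen0$genes, gen0$truth, cfg0))
  expect_true(all(vapply(r0, function(l) l$library_size, integer(1)) == 0))
})

test_that("H3K4me1 tag placement matches the closed-form normal fraction", {
  cfg <- sim_config(seed = 17L, n_genes = 20L, reads_per_mark = 100000L)
  gen <- simulate_genome(cfg)
  hc <- simulate_hcnes(gen$genes, gen$truth, cfg)
  reads <- simulate_reads(gen$genes, gen$truth, cfg, hc)
  k4me1 <- reads[[paste0("H3K4me1:", cfg$stem_cell_line)]]
  near <- merge_track(feature_track(
    hc$mouse$chrom,
    pmax(floor((hc$mouse$start + hc$mouse$end) / 2) - 1000, 0),
    floor((hc$mouse$start + hc$mouse$end) / 2) + 1000))
  frac <- sum(count_overlaps(
    data.frame(chrom = near$chrom, start = near$start, end = near$end),
    k4me1$tags)) / k4me1$library_size
  expected <- 0.9 * (stats::pnorm(1000 / 300) - stats::pnorm(-1000 / 300))
  expect_lt(abs(frac - expected), 0.02)
})

test_that("expression table is consistent with the planted truth", {
  sim <- small_sim()
  calls <- call_expression(sim$rpkm, threshold = 0.3)
  expect_identical(unname(calls$expressed),
                   unname(sim$truth$expressed))
  expect_equal(ncol(sim$rpkm) - 1L, length(sim$config$cell_lines))
})

test_that("state segmentation tiles the chromosome and encodes the truth", {
  sim <- small_sim()
  st <- sim$states
  # tiling: segments abut exactly and cover [0, chrom_length)
  expect_equal(st$start[1], 0)
  expect_equal(st$end[nrow(st)], sim$config$chrom_length)
  expect_true(all(st$start[-1] == st$end[-nrow(st)]))

  truth <- sim$truth
  # non-target expressed gene: no poised promoter near its TSS
  stem <- sim$config$stem_cell_line
  ntexp <- sim$genes[!truth$genes$is_target &
                       truth$expressed[, stem], , drop = FALSE]
  if (nrow(ntexp)) {
    w <- make_windows(ntexp, "tss", 10000)
    poised <- st[st$name == "Poised_Promoter", , drop = FALSE]
    expect_true(all(overlap_bp(w, feature_track(
      poised$chrom, poised$start, poised$end)) == 0))
  }
  # Polycomb present iff a planted bivalent gene exists
  expect_equal(any(st$name == "Polycomb_Repressed"),
               any(truth$genes$bivalent_in_stem))
  cfg_nob <- sim_config(seed = 1L, n_genes = 6L, frac_target = 0.4)
  gen <- simulate_genome(cfg_nob)
  gen$truth$genes$bivalent_in_stem[] <- FALSE
  gen$truth$expressed[gen$truth$genes$is_target,
                      cfg_nob$stem_cell_line] <- TRUE
  st2 <- simulate_states(gen$genes, gen$truth, cfg_nob)
  expect_false(any(st2$name == "Polycomb_Repressed"))
})

test_that("written outputs are reproducible byte-for-byte under one seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- sim_config(seed = 77L, n_genes = 8L, reads_per_mark = 2000L)
  m1 <- simulate_grb_data(cfg, dir = d1)$manifest
  m2 <- simulate_grb_data(cfg, dir = d2)$manifest
  expect_identical(m1$md5, m2$md5)
})
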