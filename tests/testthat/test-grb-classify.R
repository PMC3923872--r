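test_that("locus detection joins only window-overlapping, HCNE-sharing genes", {
  # disjoint windows -> all singleton loci
  far <- gene_set(c("a", "b"), "chr1", c(1e6, 2e7), c(1.1e6, 2.01e7))
  hc <- list(h = feature_track(rep("chr1", 4),
                               c(5e5, 1.2e6, 1.9e7, 2.1e7),
                               c(5e5, 1.2e6, 1.9e7, 2.1e7) + 100))
  loci <- find_multi_target_loci(far, hc, flank = 2e6)
  expect_true(all(loci$n_members == 1))

  # overlapping windows sharing an HCNE -> one two-member locus
  near <- gene_set(c("a", "b"), "chr1", c(3e6, 4e6), c(3.1e6, 4.1e6))
  shared <- list(h = feature_track("chr1", 3.5e6, 3.5e6 + 100))
  loci <- find_multi_target_loci(near, shared, flank = 2e6)
  expect_equal(loci$n_members, c(2L, 2L))
  expect_equal(length(unique(loci$locus_id)), 1L)

  # overlap without any HCNE in the intersection -> two singletons
  outside <- list(h = feature_track("chr1", 1.2e6, 1.2e6 + 100))
  loci <- find_multi_target_loci(near, outside, flank = 2e6)
  expect_true(all(loci$n_members == 1))
})

test_that("HCNE density peak lies where elements concentrate", {
  near <- gene_set(c("a", "b"), "chr1", c(3e6, 4e6), c(3.1e6, 4.1e6))
  pos <- rep(3.5e6, 20)
  hc <- list(h = feature_track(rep("chr1", 20), pos, pos + 50))
  loci <- find_multi_target_loci(near, hc, flank = 2e6)
  expect_lt(abs(loci$hcne_peak_position[1] - 3.5e6), 1e5)
})

test_that("the resolution rule reproduces the three published locus cases", {
  biv <- c(THRB = FALSE, RARB = TRUE, NR1D2 = FALSE,
           THRA = FALSE, RARA = TRUE, NR1D1 = TRUE,
           NR6A1 = FALSE, NR5A1 = FALSE)
  # one bivalent member: it alone is the target
  r1 <- resolve_locus(c("THRB", "RARB", "NR1D2"), biv)
  expect_equal(r1, c(THRB = FALSE, RARB = TRUE, NR1D2 = FALSE))
  # two bivalent members: both are targets
  r2 <- resolve_locus(c("THRA", "RARA", "NR1D1"), biv)
  expect_equal(r2, c(THRA = FALSE, RARA = TRUE, NR1D1 = TRUE))
  # no bivalent member: all members remain targets
  r3 <- resolve_locus(c("NR6A1", "NR5A1"), biv)
  expect_equal(r3, c(NR6A1 = TRUE, NR5A1 = TRUE))

  expect_error(resolve_locus("THRB", biv), ">= 2")
  expect_error(resolve_locus(c("THRB", "UNKNOWN"), biv), "missing")
})

test_that("resolution is idempotent and order-independent", {
  biv <- c(x = TRUE, y = FALSE, z = TRUE)
  a <- resolve_locus(c("x", "y", "z"), biv)
  b <- resolve_locus(c("z", "x", "y"), biv)
  expect_equal(a[sort(names(a))], b[sort(names(b))])
  expect_equal(resolve_locus(names(a)[a], biv), a[a])
})

test_that("finalize_calls integrates cluster labels and locus resolutions", {
  labels <- c(g1 = 1L, g2 = 1L, g3 = 1L, g4 = 2L)
  # no multi-member loci: final targets = cluster 1
  calls <- finalize_calls(labels)
  expect_equal(calls$final_target, c(TRUE, TRUE, TRUE, FALSE))

  loci <- data.frame(locus_id = c("L01", "L01", "L02"),
                     gene_id = c("g1", "g2", "g3"),
                     n_members = c(2L, 2L, 1L),
                     hcne_peak_position = NA_real_)
  biv <- c(g1 = TRUE, g2 = FALSE, g3 = FALSE)
  calls <- finalize_calls(labels, loci, biv)
  expect_equal(calls$final_target, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(calls$locus_id[1:3], c("L01", "L01", "L02"))
  # cluster-2 genes are never targets
  expect_false(any(calls$final_target[calls$cluster_label == 2]))
  # a gene referenced by loci but absent from labels is a contract error
  bad <- data.frame(locus_id = "L09", gene_id = "ghost", n_members = 1L,
                    hcne_peak_position = NA_real_)
  expect_error(finalize_calls(labels, bad, biv), "ghost")
})

test_that("packaged reference tables load and tally correctly", {
  ref <- grb_reference_tables()
  expect_equal(nrow(ref$table1), 48L)
  expect_equal(sum(ref$table1$cluster == 1), 25L)
  expect_equal(sum(ref$table1$cluster == 2), 23L)
  expect_setequal(unique(ref$loci$locus_id), c("L01", "L02", "L03"))
  expect_equal(nrow(ref$evidence), 8L)
  expect_equal(sum(ref$table1$mechanism %in% c("NHR", "NOR")), 48L)
})

test_that("the rule engine's family-wide tally is reported with the discrepancy", {
  res <- reference_target_calls()
  expect_equal(res$n_targets, 22L)
  expect_equal(res$published_targets, 23)
  expect_equal(res$discrepancy, -1)
  expect_setequal(res$demoted, c("THRB", "NR1D2", "THRA"))
  # demotions never touch cluster 2 and never grow cluster 1
  expect_lte(res$n_targets, sum(res$calls$cluster_label == 1))
})

test_that("crosstab conserves marginals over both axes", {
  res <- reference_target_calls()
  ref <- grb_reference_tables()
  tab <- crosstab_calls(res$calls, ref$table1, axis = "mechanism")
  expect_equal(sum(tab), 48)
  tab2 <- crosstab_calls(res$calls, ref$table1, axis = "subfamily")
  expect_equal(sum(tab2), 48)
  # targets and non-targets are both dispersed across subfamilies
  expect_gte(sum(tab2["target", ] > 0), 3)
  expect_gte(sum(tab2["non-target", ] > 0), 3)

  one_cat <- data.frame(gene = res$calls$gene_id, subfamily = "all",
                        mechanism = "all")
  t1 <- crosstab_calls(res$calls, one_cat, axis = "subfamily")
  expect_equal(dim(t1), c(2L, 1L))
  expect_equal(sum(t1), 48)
})

test_that("synthetic locus sharing resolves with planted bivalency", {
  cfg <- sim_config(seed = 19L, n_genes = 20L, locus_sharing = TRUE,
                    n_shared_pairs = 2L, reads_per_mark = 20000L)
  sim <- simulate_grb_data(cfg)
  mat <- build_count_matrix(sim$genes, sim$hcnes)
  cl <- hcne_cluster(hcne_dissimilarity(mat), mat)
  c1 <- sim$genes[cl$labels[sim$genes$gene_id] == 1, , drop = FALSE]
  loci <- find_multi_target_loci(c1, sim$hcnes)
  expect_gte(sum(loci$n_members > 1), 2L)

  stem <- cfg$stem_cell_line
  k4 <- promoter_counts(sim$genes, sim$reads[[paste0("H3K4me3:", stem)]])
  k27 <- promoter_counts(sim$genes, sim$reads[[paste0("H3K27me3:", stem)]])
  rec <- classify_bivalency(data.frame(gene_id = sim$genes$gene_id,
                                       k4me3 = unname(k4),
                                       k27me3 = unname(k27)))
  biv <- stats::setNames(rec$bivalent, rec$gene_id)
  calls <- finalize_calls(cl$labels, loci, biv)
  # within multi-member loci with a bivalent member, only those survive
  for (lid in unique(loci$locus_id[loci$n_members > 1])) {
    members <- loci$gene_id[loci$locus_id == lid]
    if (any(biv[members])) {
      expect_equal(calls$final_target[match(members, calls$gene_id)],
                   unname(biv[members]))
    } else {
      expect_true(all(calls$final_target[match(members, calls$gene_id)]))
    }
  }
})
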