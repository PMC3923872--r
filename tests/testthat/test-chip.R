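make_lib <- function(pos, strand = "+", fragment_size = 200) {
  tag_library(feature_track(rep("chr1", length(pos)), pos, pos + 1,
                            strand = rep_len(strand, length(pos))),
              fragment_size = fragment_size)
}

test_that("extend_tags is strand-aware and clipped", {
  lib <- make_lib(c(1000, 1000, 50), c("+", "-", "-"))
  fr <- extend_tags(lib)
  fr <- fr[order(fr$start), ]
  expect_equal(fr$start, c(0, 801, 1000))
  expect_equal(fr$end, c(51, 1001, 1200))

  lib1 <- make_lib(c(10, 20), c("+", "-"), fragment_size = 1)
  fr1 <- extend_tags(lib1)
  expect_equal(fr1$start, c(10, 20))
  expect_equal(fr1$end, c(11, 21))
})

test_that("binned coverage normalizes by library size", {
  empty <- tag_library(feature_track(), fragment_size = 200)
  expect_equal(binned_coverage(empty, "chr1", 0, 1000, 100), numeric(10))

  lib <- make_lib(c(150, 450, 450))
  v <- binned_coverage(lib, "chr1", 0, 1000, 100)
  lib2 <- make_lib(rep(c(150, 450, 450), 2))  # duplicated library
  expect_equal(binned_coverage(lib2, "chr1", 0, 1000, 100), v)
})

test_that("binned coverage matches a per-base brute-force oracle", {
  set.seed(41)
  for (rep in 1:10) {
    pos <- sample(0:9999, 60, replace = TRUE)
    strand <- sample(c("+", "-"), 60, replace = TRUE)
    lib <- make_lib(pos, strand, fragment_size = 150)
    v <- binned_coverage(lib, "chr1", 1000, 5000, 200)
    frags <- extend_tags(lib)
    expected <- vapply(seq(1000, 4800, by = 200), function(bs) {
      brute_count("chr1", bs, bs + 200, frags) * 1e6 / lib$library_size
    }, numeric(1))
    expect_equal(v, expected)
  }
})

test_that("average_profile averages per-gene vectors in TSS orientation", {
  g1 <- gene_set("a", "chr1", 50000, 60000, "+")
  lib <- make_lib(c(50500, 50500, 52000))
  single <- average_profile(g1, lib, "tss", flank = 5000, bin = 500)
  expect_equal(single$values,
               binned_coverage(lib, "chr1", 45000, 55000, 500))

  g2 <- gene_set(c("a", "b"), "chr1", c(50000, 50000), c(60000, 60000),
                 c("+", "-"))
  both <- average_profile(g2, lib, "tss", flank = 5000, bin = 500)
  va <- binned_coverage(lib, "chr1", 45000, 55000, 500)
  vb <- rev(binned_coverage(lib, "chr1", 54999, 64999, 500))
  expect_equal(both$values, (va + vb) / 2)
})

test_that("synthetic H3K4me3 profile peaks at the TSS", {
  sim <- small_sim()
  stem <- sim$config$stem_cell_line
  expr <- sim$genes[sim$truth$expressed[, stem], , drop = FALSE]
  pr <- average_profile(expr, sim$reads[[paste0("H3K4me3:", stem)]],
                        "tss", flank = 10000, bin = 100)
  peak_pos <- pr$positions[which.max(pr$values)]
  expect_lte(abs(peak_pos), 1000)
})

test_that("background pool concatenates and de-duplicates by gene_id", {
  a <- gene_set(paste0("a", 1:10), "chr1", (1:10) * 1000, (1:10) * 1000 + 10)
  b <- gene_set(paste0("b", 1:5), "chr1", (1:5) * 100, (1:5) * 100 + 10)
  expect_equal(nrow(build_background_pool(a, b)), 15L)
  b2 <- gene_set(c("a1", "a2", "b9"), "chr1", c(0, 10, 20) + 1,
                 c(5, 15, 25) + 1)
  expect_equal(nrow(build_background_pool(a, b2)), 11L)
  expect_identical(build_background_pool(a, b),
                   build_background_pool(b, a))
})

test_that("bootstrap null is degenerate on a single-gene pool", {
  g <- gene_set("only", "chr1", 5000, 6000)
  lib <- make_lib(rep(5000, 7))  # 7 tags at the TSS
  null <- bootstrap_null(g, lib, width = 1000, B = 50, n = 3, seed = 1)
  expect_true(all(null$statistic_values == log2(8)))
  expect_equal(null$q95, log2(8))
})

test_that("bootstrap null is deterministic given the seed", {
  sim <- small_sim()
  lib <- sim$reads[[paste0("H3K4me1:", sim$config$stem_cell_line)]]
  n1 <- bootstrap_null(sim$genes, lib, 1e4, B = 200, n = 10, seed = 99)
  n2 <- bootstrap_null(sim$genes, lib, 1e4, B = 200, n = 10, seed = 99)
  expect_identical(n1$q95, n2$q95)
  expect_identical(n1$statistic_values, n2$statistic_values)
  expect_error(bootstrap_null(gene_set(character(0), character(0),
                                       numeric(0), numeric(0)),
                              lib, 1e4, n = 5), "empty")
})

test_that("enrichment_call applies the critical region consistently", {
  g <- gene_set(c("x", "y"), "chr1", c(1000, 9000), c(2000, 9500))
  lib <- make_lib(c(1000, 1001, 9000))
  null <- bootstrap_null(g, lib, 500, B = 100, n = 2, seed = 3)
  call <- enrichment_call(g, lib, null)
  expect_identical(call$outside_critical, call$log2_mean > null$q95)

  # all-zero counts with a positive critical value stay inside
  far <- gene_set("far", "chr1", 5e5, 5.1e5)
  call0 <- enrichment_call(far, lib, null)
  expect_false(call0$outside_critical)
})

test_that("adding tags inside the evaluated windows never demotes a call", {
  set.seed(43)
  g <- gene_set(c("x", "y"), "chr1", c(10000, 30000), c(12000, 32000))
  lib <- make_lib(sample(0:40000, 200, replace = TRUE))
  null <- bootstrap_null(g, lib, 2000, B = 200, n = 2, seed = 5)
  base <- enrichment_call(g, lib, null)
  boosted <- make_lib(c(lib$tags$start, rep(c(10000, 30000), 50)))
  call2 <- enrichment_call(g, boosted, null)
  expect_gte(call2$log2_mean, base$log2_mean)
})

test_that("CpG stratification partitions the gene set", {
  sim <- small_sim()
  parts <- stratify_by_cpg(sim$genes, sim$cpg)
  expect_equal(nrow(parts$cpg) + nrow(parts$noncpg), nrow(sim$genes))
  expect_equal(nrow(stratify_by_cpg(sim$genes, feature_track())$cpg), 0L)
  g <- gene_set("g", "chr1", 1000, 2000)
  covering <- feature_track("chr1", 900, 1100)  # covers the TSS
  expect_equal(stratify_by_cpg(g, covering)$cpg$gene_id, "g")
})

test_that("peak filtering keeps significant, top-scoring peaks", {
  pk <- feature_track(rep("chr1", 6), (1:6) * 1000, (1:6) * 1000 + 100,
                      score = c(9, 3, 7, 5, 1, 8),
                      extra = data.frame(
                        pvalue = c(1e-5, 0.5, 1e-4, 1e-4, 0.9, 0.01)))
  expect_equal(nrow(filter_peaks(pk, top_n = 10, max_p = 0.001)), 3L)
  kept <- filter_peaks(pk, top_n = 2, max_p = 0.001)
  expect_setequal(kept$score, c(9, 7))
  expect_equal(nrow(filter_peaks(pk, max_p = 1e-9)), 0L)
  expect_error(filter_peaks(feature_track("chr1", 0, 10)), "pvalue")

  # mixed random instance vs a sort-and-slice oracle
  set.seed(44)
  n <- 200
  pk2 <- feature_track(rep("chr1", n), (1:n) * 10, (1:n) * 10 + 5,
                       score = runif(n),
                       extra = data.frame(pvalue = runif(n, 0, 0.01)))
  got <- filter_peaks(pk2, top_n = 50, max_p = 0.005)
  pass <- pk2[pk2$pvalue < 0.005, ]
  oracle <- sort(utils::head(sort(pass$score, decreasing = TRUE), 50))
  expect_equal(sort(got$score), oracle)
})
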