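test_that("the Hp shuffle threshold is seeded, reproducible, and ranked", {
  set.seed(51)
  blocks <- data.frame(sum_nmax = sample(20:40, 20, TRUE),
                       sum_nmin = sample(0:15, 20, TRUE))
  th1 <- hp_shuffle_threshold(blocks, scan_window_blocks = 5, n_shuffles = 100,
                              rank = 5, seed = 99)
  th2 <- hp_shuffle_threshold(blocks, scan_window_blocks = 5, n_shuffles = 100,
                              rank = 5, seed = 99)
  expect_identical(th1, th2)
  # brute-force recomputation with the same RNG stream
  mins <- local({
    old <- .Random.seed
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(99)
    vapply(1:100, function(i) {
      perm <- sample.int(20)
      g <- rep(1:4, each = 5)
      smax <- rowsum(blocks$sum_nmax[perm], g)[, 1]
      smin <- rowsum(blocks$sum_nmin[perm], g)[, 1]
      min(2 * smax * smin / (smax + smin)^2)
    }, numeric(1))
  })
  expect_equal(th1$cutoff, sort(mins)[5])
  expect_equal(th1$minima, sort(mins))
  # all-identical blocks: every shuffle minimum is that constant
  cb <- data.frame(sum_nmax = rep(30, 20), sum_nmin = rep(10, 20))
  thc <- hp_shuffle_threshold(cb, 5, n_shuffles = 50, rank = 3, seed = 1)
  expect_equal(unique(thc$minima), 2 * 150 * 50 / 200^2)
  # rank 50 of 1000 implies the 0.05 level
  expect_equal(th1$implied_level, 0.05)
  expect_error(hp_shuffle_threshold(blocks, 5, n_shuffles = 3, rank = 5, seed = 1),
               "n_shuffles")
  expect_error(hp_shuffle_threshold(blocks, 5), "seed")
  expect_error(hp_shuffle_threshold(blocks[1:3, ], 5, seed = 1), "fewer blocks")
})

test_that("shuffle minima are invariant to block labeling (relabeling rows)", {
  set.seed(53)
  blocks <- data.frame(sum_nmax = sample(20:40, 30, TRUE),
                       sum_nmin = sample(0:15, 30, TRUE))
  th_a <- hp_shuffle_threshold(blocks, 6, n_shuffles = 200, rank = 10, seed = 5)
  th_b <- hp_shuffle_threshold(blocks[sample(30), ], 6, n_shuffles = 200,
                               rank = 10, seed = 5)
  # distributions agree (same multiset of blocks): compare via KS distance
  expect_gt(suppressWarnings(ks.test(th_a$minima, th_b$minima))$p.value, 0.01)
})

test_that("per-method thresholds flag the stated quantiles with tie inclusion", {
  vals <- c(seq_len(200) / 10)
  th <- suppressWarnings(per_method_threshold(vals, "bottommost", q = 0.01))
  expect_equal(th$n_flagged, 2L)
  expect_equal(which(th$flagged), 1:2)
  th_top <- suppressWarnings(per_method_threshold(vals, "topmost", q = 0.01))
  expect_equal(which(th_top$flagged), 199:200)
  # all-equal statistics: everything ties at the cutoff and is flagged
  expect_warning(th_eq <- per_method_threshold(rep(1, 150), "bottommost"),
                 "degenerate")
  expect_equal(th_eq$n_flagged, 150L)
  # missing windows are excluded before the quantile
  vals_na <- c(vals, rep(NA, 50))
  th_na <- suppressWarnings(per_method_threshold(vals_na, "bottommost", 0.01))
  expect_equal(which(th_na$flagged), 1:2)
  expect_warning(per_method_threshold(1:50 / 10, "bottommost"), "fewer than 100")
})

test_that("consensus requires two methods and intersects their intervals", {
  w <- function(s, e) data.frame(chrom = rep("1", length(s)), start = s, end = e)
  # hp-only flag: not a sweep
  res1 <- call_consensus_sweeps(list(hp = w(0, 40000), tajima_d = w(numeric(0), numeric(0))))
  expect_equal(nrow(res1), 0)
  # overlapping hp and ihs windows: sweep is the intersection with both ids
  res2 <- call_consensus_sweeps(list(hp = w(0, 40000), ihs = w(20000, 60000),
                                     clr = w(200000, 240000)))
  expect_equal(nrow(res2), 1)
  expect_equal(res2$start, 20000); expect_equal(res2$end, 40000)
  expect_setequal(strsplit(res2$support, ",")[[1]], c("hp", "ihs"))
  # three-interval fixture: adjacency merging before intersection gives two
  # maximal regions separated by the singly-covered gap
  res3 <- call_consensus_sweeps(list(
    hp = w(c(0, 20000), c(40000, 60000)),        # merges to [0, 60000)
    tajima_d = w(50000, 90000),
    fay_wu_h = w(80000, 120000)))
  expect_equal(res3$start, c(50000, 80000))
  expect_equal(res3$end, c(60000, 90000))
  expect_equal(res3$n_methods, c(2L, 2L))
  # every emitted region has >= 2 supporting methods (output invariant)
  bundles <- sweep_bundles(20)
  for (b in bundles[1:5]) {
    if (nrow(b$scan$sweeps) > 0) expect_true(all(b$scan$sweeps$n_methods >= 2))
  }
})

test_that("the four-rule PSG filter matches brute-force rule application", {
  # hand-built scene: sweep [10000, 30000)
  #   gHit  12000-14000 (+2 kb promoter 10000-12000)
  #   gWeak 18000-26000 (+2 kb promoter 16000-18000)
  #   gFar  80000-82000, outside the sweep
  sweeps <- data.frame(chrom = "1", start = 10000, end = 30000,
                       support = "hp,tajima_d", n_methods = 2L)
  genes <- data.frame(gene_id = c("gHit", "gWeak", "gFar"), chrom = "1",
                      strand = "+", start = c(12000, 18000, 80000),
                      end = c(14000, 26000, 82000), stringsAsFactors = FALSE)
  no_feats <- data.frame(gene_id = character(0), chrom = character(0),
                         start = numeric(0), end = numeric(0),
                         type = character(0), stringsAsFactors = FALSE)
  idx <- annotation_index(genes, no_feats, c("1" = 1e5))
  kb <- make_windows(c("1" = 1e5), 1000, 1000)
  # descending baseline keeps the bottommost minimum unique (last window)
  # when extremes are knocked out; extremes override at -9 (bottom), 99 (top)
  mk <- function(extreme_at, low_snp_at = integer(0), top_at = integer(0)) {
    st <- data.frame(kb, snp_count = 5L, value = 1 - 1e-6 * kb$start)
    st$value[kb$start %in% extreme_at] <- -9
    st$value[kb$start %in% top_at] <- 99
    st$snp_count[kb$start %in% low_snp_at] <- 1L
    st
  }
  kb_stats <- list(
    hp = mk(seq(17000, 22000, 1000)),        # 6 windows over gWeak+promoter < 10
    tajima_d = mk(15000),                    # flagged window touches no gene
    fay_wu_h = mk(c(12000, 13000)),          # strong evidence at gHit
    clr = mk(integer(0), top_at = 27000))    # topmost flag touches no gene
  ihs_rec <- data.frame(site = 1L, chrom = "1", pos = 99000L, ihs = -3)
  res <- suppressWarnings(
    filter_psgs(sweeps, idx, kb_stats, ihs_rec, min_weak_windows = 10))
  expect_true("gHit" %in% res$gene_id)          # rule: fay_wu_h selected windows
  expect_false("gWeak" %in% res$gene_id)        # only 6 Hp windows (< 10)
  expect_false("gFar" %in% res$gene_id)         # outside sweeps; iHS SNP not in sweep
  tr <- res[res$gene_id == "gHit", ]
  expect_equal(tr$n_fay_wu_h, 2L)
  expect_true(tr$passed_strong)
  # 1-kb windows with < 2 SNPs are discarded before selection
  kb2 <- kb_stats
  kb2$fay_wu_h <- mk(c(12000, 13000), low_snp_at = c(12000, 13000))
  res2 <- suppressWarnings(
    filter_psgs(sweeps, idx, kb2, ihs_rec, min_weak_windows = 10))
  expect_false("gHit" %in% res2$gene_id)
  # rule 4: an iHS < -2 SNP inside the sweep rescues its gene
  ihs_in <- data.frame(site = 1L, chrom = "1", pos = 12500L, ihs = -2.5)
  res3 <- suppressWarnings(
    filter_psgs(sweeps, idx, kb2, ihs_in, min_weak_windows = 10))
  expect_true("gHit" %in% res3$gene_id)
  expect_true(res3$rescued_by_ihs[res3$gene_id == "gHit"])
  expect_equal(res3$n_ihs_snps[res3$gene_id == "gHit"], 1L)
})

test_that("PSG output is confined to sweep-overlapping or iHS-rescued genes", {
  bundles <- sweep_bundles(20)
  b <- bundles[[1]]
  res <- generate_resources(L = b$sim$config$L, n_genes = 30, n_sets = 5, seed = 501)
  kb_stats <- sweep_kb_stats(b$sim$gt, b$anc, "domestic",
                             c("1" = b$sim$config$L), scan = b$scan$clr_scan)
  if (nrow(b$scan$sweeps) > 0) {
    psgs <- suppressWarnings(filter_psgs(b$scan$sweeps, res$index, kb_stats,
                                         b$scan$ihs_records))
    overlapping <- genes_overlapping(res$index, b$scan$sweeps)
    expect_true(all(psgs$gene_id %in% overlapping))
    # each trace re-evaluates to a pass
    if (nrow(psgs) > 0)
      expect_true(all(psgs$passed_strong | psgs$passed_weak | psgs$rescued_by_ihs))
  } else succeed("no consensus sweep in this replicate")
})

test_that("neutral consensus false positives stay within the per-method budget", {
  sims <- neutral_sims(20)
  for (sim in sims[1:2]) {
    anc <- rep("ref", n_sites(sim$gt))
    sc <- scan_cohort(sim$gt, anc, "domestic", c("1" = sim$config$L), seed = 71)
    budget <- sum(vapply(sc$flagged, nrow, integer(1)))
    expect_lte(nrow(sc$sweeps), budget)
  }
})
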