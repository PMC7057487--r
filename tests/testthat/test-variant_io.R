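test_that("VCF round trip preserves genotypes, positions, alleles and phase", {
  set.seed(42)
  hap <- matrix(rbinom(4 * 6, 1, 0.4), nrow = 4)
  gt <- toy_gt(hap, positions = c(10L, 50L, 99L, 120L, 5000L, 70000L),
               pops = c("wild", "domestic"))
  f <- tempfile(fileext = ".vcf")
  write_vcf_gt(gt, f, contig_lengths = c("1" = 1e5))
  gt2 <- read_vcf(f, gt$samples)
  expect_identical(unname(gt2$haplotypes), unname(gt$haplotypes))
  expect_identical(gt2$positions, gt$positions)
  expect_identical(gt2$ref, gt$ref)
  expect_identical(gt2$alt, gt$alt)
  expect_true(gt2$phased)
})

test_that("multiallelic and indel records are dropped with a count", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\t.\tA\tG\t50\tPASS\t.\tGT\t0|1\t1|1",
    "1\t200\t.\tA\tT,G\t50\tPASS\t.\tGT\t0|1\t0|2",
    "1\t300\t.\tAT\tA\t50\tPASS\t.\tGT\t0|1\t0|0",
    "1\t400\t.\tC\tT\t50\tPASS\t.\tGT\t0|0\t."), f)
  gt <- read_vcf(f)
  expect_equal(n_sites(gt), 2L)
  expect_equal(unname(attr(gt, "dropped")[["non_biallelic_or_indel"]]), 2)
  expect_true(is.na(gt$haplotypes[3, 2]))  # missing call preserved as NA
})

test_that("unsorted input and unknown samples are rejected with context", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "1\t500\t.\tA\tG\t50\tPASS\t.\tGT\t0|1",
    "1\t100\t.\tC\tT\t50\tPASS\t.\tGT\t0|1"), f)
  expect_error(read_vcf(f), "not sorted.*1:100")
  f2 <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "1\t100\t.\tA\tG\t50\tPASS\t.\tGT\t0|1"), f2)
  expect_error(read_vcf(f2, data.frame(sample = c("s1", "ghost"),
                                       population = "wild")),
               "unknown sample.*ghost")
})

test_that("site filters apply the five rules with exact boundary semantics", {
  # depth must be strictly < 100; the other thresholds are inclusive
  s_depth <- data.frame(qual = 50, depth = 150, base_q = 30, map_q = 30, alt_reads = 5)
  expect_equal(apply_site_filters(s_depth)$report$n_kept, 0)
  s_boundary <- data.frame(qual = 20, depth = 50, base_q = 20, map_q = 10, alt_reads = 3)
  expect_equal(apply_site_filters(s_boundary)$report$n_kept, 1)
  s_d100 <- data.frame(qual = 20, depth = 100, base_q = 20, map_q = 10, alt_reads = 3)
  expect_equal(apply_site_filters(s_d100)$report$n_kept, 0)
})

test_that("a 10-record fixture keeps exactly the hand-enumerated sites", {
  fx <- data.frame(
    qual      = c(50, 19, 50, 50, 50, 50, 20, 50, 50, 50),
    depth     = c(40, 40, 100, 40, 40, 40, 99, 40, 40, 150),
    base_q    = c(30, 30, 30, 19, 30, 30, 20, 30, 30, 30),
    map_q     = c(20, 20, 20, 20, 9, 20, 10, 20, 20, 20),
    alt_reads = c(5, 5, 5, 5, 5, 2, 3, 5, NA, 5))
  # by hand: rows 2 (qual), 3 (depth), 4 (bq), 5 (mq), 6 (alt), 9 (missing),
  # 10 (depth) fail -> rows 1, 7, 8 kept... row 7 is all-boundary and passes
  res <- apply_site_filters(fx)
  expect_equal(which(res$keep), c(1L, 7L, 8L))
  expect_equal(unname(res$report$failed["depth"]), 2)
  expect_equal(unname(res$report$missing["alt_reads"]), 1)
})

test_that("site filtering is order-independent and idempotent", {
  set.seed(7)
  fx <- data.frame(qual = sample(c(10, 30), 50, TRUE), depth = sample(c(50, 120), 50, TRUE),
                   base_q = sample(c(15, 25), 50, TRUE), map_q = sample(c(5, 15), 50, TRUE),
                   alt_reads = sample(0:6, 50, TRUE))
  res <- apply_site_filters(fx)
  perm <- sample(nrow(fx))
  res_perm <- apply_site_filters(fx[perm, ])
  expect_equal(sort(rownames(res$kept)), sort(rownames(res_perm$kept)))
  res2 <- apply_site_filters(res$kept)
  expect_equal(res2$kept, res$kept)
  expect_equal(res2$report$n_kept, res$report$n_kept)
})

test_that("LD pruning removes duplicated columns and keeps independent ones", {
  set.seed(11)
  base <- matrix(rbinom(20 * 8, 1, 0.5), nrow = 20)
  dup <- cbind(base[, 1:4], base[, 2], base[, 5:8])  # col 5 duplicates col 2
  gt <- toy_gt(dup)
  pr <- ld_prune(gt, window_snps = 9, step_snps = 2)
  expect_false(all(c(2L, 5L) %in% pr$keep))
  expect_true(xor(2L %in% pr$keep, 5L %in% pr$keep))
  # orthogonal deterministic columns: all retained
  h <- matrix(0L, 8, 4); for (j in 1:4) h[c(2 * j - 1, 2 * j), j] <- 1L
  pr2 <- ld_prune(toy_gt(h), window_snps = 4, step_snps = 1, r2_max = 0.2)
  expect_equal(pr2$keep, 1:4)
})

test_that("LD pruning matches the exhaustive pairwise oracle on one window", {
  set.seed(13)
  h <- matrix(rbinom(30 * 10, 1, 0.5), nrow = 30)
  h[, 4] <- h[, 2]; h[, 7] <- 1L - h[, 2]  # a correlated triple
  gt <- toy_gt(h)
  pr <- ld_prune(gt, window_snps = 10, step_snps = 5)
  expect_equal(pr$keep, oracle_ld_keep(h))
  # retained set is a subset of input indices and no retained pair exceeds r2
  expect_true(all(pr$keep %in% 1:10))
  r2 <- cor(h[, pr$keep])^2
  expect_true(all(r2[upper.tri(r2)] <= 0.1 + 1e-12))
})

test_that("monomorphic sites are retained and logged by ld_prune", {
  h <- cbind(rep(0L, 10), rbinom(10, 1, 0.5), rep(1L, 10))
  while (sd(h[, 2]) == 0) h[, 2] <- rbinom(10, 1, 0.5)
  pr <- ld_prune(toy_gt(h), window_snps = 3, step_snps = 1)
  expect_true(all(c(1L, 3L) %in% pr$keep))
  expect_equal(pr$n_monomorphic, 2)
})

test_that("window tiling follows the half-step scheme with terminal clipping", {
  w <- make_windows(c(chr = 1e5), 40000, 20000)
  expect_equal(w$start, c(0, 20000, 40000, 60000))
  expect_equal(w$end[4], 1e5)
  expect_equal(nrow(make_windows(c(chr = 25000), 40000)), 1)
  expect_equal(make_windows(c(chr = 25000), 40000)$end, 25000)
  kb <- make_windows(c(chr = 10000), 1000, 1000)
  expect_equal(nrow(kb), 10)
  expect_true(all(kb$end - kb$start == 1000))
  expect_error(make_windows(c(chr = 1e5), 1000, 2000), "step")
})

test_that("position categories follow precedence and are total", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "1",
                      strand = c("+", "-"), start = c(5000, 20000),
                      end = c(9000, 26000), stringsAsFactors = FALSE)
  feats <- rbind(
    data.frame(gene_id = "gA", chrom = "1", start = 5000, end = 6000, type = "exon"),
    data.frame(gene_id = "gA", chrom = "1", start = 6000, end = 6002, type = "splicing"),
    data.frame(gene_id = "gA", chrom = "1", start = 6002, end = 7998, type = "intron"),
    data.frame(gene_id = "gA", chrom = "1", start = 7998, end = 8000, type = "splicing"),
    data.frame(gene_id = "gA", chrom = "1", start = 8000, end = 9000, type = "exon"),
    data.frame(gene_id = "gA", chrom = "1", start = 4000, end = 5000, type = "upstream"),
    data.frame(gene_id = "gA", chrom = "1", start = 9000, end = 10000, type = "downstream"),
    data.frame(gene_id = "gB", chrom = "1", start = 20000, end = 26000, type = "exon"),
    data.frame(gene_id = "gB", chrom = "1", start = 26000, end = 27000, type = "upstream"),
    data.frame(gene_id = "gB", chrom = "1", start = 19000, end = 20000, type = "downstream"))
  idx <- annotation_index(genes, feats, c("1" = 50000))
  expect_equal(classify_positions(idx, "1", 5500), "exon")
  # 500 bp beyond the minus-strand gene's 3'-most genomic coordinate is its
  # (strand-aware) upstream side
  expect_equal(classify_positions(idx, "1", 26500), "upstream")
  expect_equal(classify_positions(idx, "1", 40000), "intergenic")
  expect_equal(classify_positions(idx, "1", 6001), "splicing")
  # totality: every position gets exactly one category
  cls <- classify_positions(idx, "1", 1:50000)
  expect_equal(length(cls), 50000)
  expect_true(all(cls %in% c("exon", "splicing", "UTR5", "UTR3", "intron",
                             "upstream", "downstream", "intergenic")))
  fr <- region_fractions(idx)
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr["exon"]), (1000 + 1000 + 6000) / 50000)
  # promoters: 2 kb upstream of the strand-aware start
  g <- idx$genes
  expect_equal(g$prom_start[1], 3000); expect_equal(g$prom_end[1], 5000)
  expect_equal(g$prom_start[2], 26000); expect_equal(g$prom_end[2], 28000)
  expect_error(annotation_index(genes, rbind(feats,
    data.frame(gene_id = "gA", chrom = "1", start = 49000, end = 51000,
               type = "exon")), c("1" = 50000)), "outside contig")
})

test_that("GFF3 written by the package reloads with identical derived features", {
  res <- generate_resources(L = 2e5, n_genes = 5, n_sets = 3, seed = 77)
  f <- tempfile(fileext = ".gff3")
  domestiscan:::write_gff3(res$genes, res$features, f)
  idx <- load_annotations(f, c("1" = 2e5))
  expect_equal(idx$genes$gene_id, res$genes$gene_id)
  expect_equal(idx$genes$start, res$genes$start)
  set.seed(1)
  pos <- sample.int(2e5, 500)
  expect_equal(classify_positions(idx, "1", pos),
               classify_positions(res$index, "1", pos))
})
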