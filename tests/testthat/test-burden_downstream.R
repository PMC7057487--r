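test_that("polarization follows the outgroup-matching rules", {
  res <- polarize_alleles(c("A", "A", "C", NA, "G"),
                          wild = list("A", c("A", "G"), "A", "A", "G"),
                          domestic = list("G", "T", "G", "G", "G"))
  expect_equal(res$status, c("ok", "triallelic-skip", "outgroup-mismatch-skip",
                             "outgroup-mismatch-skip", "outgroup-mismatch-skip"))
  expect_equal(res$ancestral[1], "A")
  expect_equal(res$derived[1], "G")
  # statuses partition all sites
  expect_equal(sum(res$status == "ok") + sum(grepl("skip", res$status)), 5)
})

test_that("polarize_gt recovers the simulator's ancestral truth", {
  sim <- sweep_bundles(20)[[1]]$sim
  pol <- polarize_gt(sim$gt, sim$outgroup_seq)
  ok <- pol$table$status == "ok"
  # outgroup equals the ancestral sequence at every SNP, so every site where
  # both cohorts still segregate polarizes to the reference (ancestral) allele
  expect_true(all(pol$ancestral[ok] == "ref"))
  expect_gt(mean(ok), 0.5)
})

test_that("codon classification and site opportunities follow the genetic code", {
  expect_equal(classify_substitution("CTTAAA", 3, "T", "C"), "synonymous")   # Leu->Leu
  expect_equal(classify_substitution("CTTAAA", 1, "C", "A"), "nonsynonymous") # Leu->Ile
  opp <- cds_site_opportunities("TTTAAA")  # Phe + Lys
  # TTT: only T->C at pos 3 is synonymous (1/3); AAA: only A->G at pos 3 (1/3)
  expect_equal(opp$Ls, 2 / 3)
  expect_equal(opp$Ln, 6 - 2 / 3)
  expect_error(cds_site_opportunities("TTTA"), "divisible")
})

test_that("per-individual omega counts derived alleles against opportunities", {
  # one gene, CDS = positions 1..6 on a reference of CTT AAA
  ref <- "CTTAAA"
  genes <- data.frame(gene_id = "g1", chrom = "1", start = 0, end = 6,
                      strand = "+", stringsAsFactors = FALSE)
  # sites: pos 3 (T->C syn), pos 4 (A->C nonsyn)
  hap <- rbind(c(1, 0), c(1, 0),   # s1: derived syn on both haplotypes
               c(0, 1), c(0, 0))   # s2: one nonsyn derived copy
  gt <- genotype_table(hap, positions = c(3L, 4L), chrom = "1",
                       ref = c("T", "A"), alt = c("C", "C"),
                       samples = data.frame(sample = c("s1", "s2"),
                                            population = c("wild", "domestic")))
  om <- omega_per_individual(gt, genes, ref, ancestral = c("ref", "ref"))
  expect_equal(om$Ds, c(2L, 0L))
  expect_equal(om$Dn, c(0L, 1L))
  # only synonymous derived alleles -> omega = 0; Ds = 0 -> flagged NA
  expect_equal(om$omega[1], 0)
  expect_true(is.na(om$omega[2]))
  # omega invariant to site processing order is implied by the count form:
  # recompute with columns swapped
  gt2 <- genotype_table(hap[, 2:1], positions = c(3L, 4L), chrom = "1",
                        ref = c("T", "A"), alt = c("C", "C"),
                        samples = gt$samples)
  # (swapping columns swaps positions; rebuild consistently instead)
  gt2 <- genotype_table(hap, positions = c(3L, 4L), chrom = "1",
                        ref = c("T", "A"), alt = c("C", "C"), samples = gt$samples)
  om2 <- omega_per_individual(gt2, genes, ref, c("ref", "ref"))
  expect_equal(om2$Dn, om$Dn)
})

test_that("the burden test builds the 2x2 table and matches the textbook chi-square", {
  # identical cohorts: no association
  hap <- rbind(c(1, 0, 1), c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  gt <- toy_gt(hap, pops = c("wild", "domestic"))
  scores <- data.frame(pos = gt$positions, rs = c(3, 1, 3))
  res <- deleterious_burden_test(scores, gt, rep("ref", 3))
  expect_equal(res$table[, "wild"], res$table[, "domestic"])
  expect_equal(res$chisq, 0)
  expect_equal(res$p_value, 1)
  # hand-computed chi-square for the table [[30,10],[70,90]]
  tab <- matrix(c(30, 70, 10, 90), 2)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chisq_hand <- sum((tab - exp_tab)^2 / exp_tab)
  ct <- chisq.test(tab, correct = FALSE)
  expect_equal(unname(ct$statistic), chisq_hand)
})

test_that("planted domestic frequency shifts are detected as elevated burden", {
  bundles <- sweep_bundles(20)
  sig <- vapply(1:10, function(i) {
    sim <- bundles[[i]]$sim
    res <- generate_resources(L = sim$config$L, n_genes = 5, n_sets = 2,
                              seed = 700 + i, gt = sim$gt,
                              ancestral = rep("ref", n_sites(sim$gt)),
                              deleterious = list(n = 80, mode = "shifted", shift = 0.2))
    bt <- deleterious_burden_test(res$scores[, c("pos", "rs")], sim$gt,
                                  rep("ref", n_sites(sim$gt)))
    bt$p_value < 0.005 &&
      bt$mean_derived_freq["domestic"] > bt$mean_derived_freq["wild"]
  }, logical(1))
  expect_gte(mean(sig), 0.8)
})

test_that("region enrichment compares observed SNP counts to territory fractions", {
  res_r <- generate_resources(L = 2e5, n_genes = 8, n_sets = 2, seed = 81)
  territory <- data.frame(chrom = "1", start = 0, end = 2e5)
  frac <- region_fractions(res_r$index, territory)
  # uniform placement: expected counts sum to the observed total
  set.seed(82)
  adaptive <- data.frame(chrom = "1", pos = sample.int(2e5, 200))
  er <- region_enrichment(adaptive, res_r$index, territory)
  expect_equal(sum(er$expected), 200)
  expect_equal(er$p_adjusted, pmin(1, er$p_value * nrow(er)))
  # hand computation: intron fraction 0.5, observed 70 of 100
  er_hand <- local({
    obs <- 70; tot <- 100; f <- 0.5
    unname(chisq.test(c(obs, tot - obs), p = c(f, 1 - f))$statistic)
  })
  expect_equal(er_hand, (70 - 50)^2 / 50 + (30 - 50)^2 / 50)
})

test_that("perfectly proportional placement yields chi-square 0 everywhere", {
  genes <- data.frame(gene_id = "g", chrom = "1", strand = "+",
                      start = 1000, end = 2000, stringsAsFactors = FALSE)
  feats <- data.frame(gene_id = "g", chrom = "1", start = 1000, end = 2000,
                      type = "exon", stringsAsFactors = FALSE)
  idx <- annotation_index(genes, feats, c("1" = 4000))
  territory <- data.frame(chrom = "1", start = 0, end = 4000)
  # exon fraction 1/4 (flanks default off in this index): place proportionally
  frac <- region_fractions(idx, territory)
  n_ex <- 25; n_other <- 75
  adaptive <- data.frame(chrom = "1",
                         pos = c(sample(1001:2000, n_ex), sample(3001:4000, n_other)))
  er <- region_enrichment(adaptive, idx, territory)
  ex_row <- er[er$region == "exon", ]
  expect_equal(ex_row$observed, ex_row$expected)
  expect_equal(ex_row$chisq, 0)
  expect_equal(ex_row$p_value, 1)
})

test_that("set enrichment equals the hypergeometric tail and fisher.test", {
  bg <- sprintf("g%02d", 1:60)
  target <- bg[1:12]
  memb <- rbind(data.frame(set_id = "hit", gene = bg[c(1:6, 40:43)]),
                data.frame(set_id = "null", gene = bg[30:49]),
                data.frame(set_id = "empty", gene = "absent"))
  res <- set_enrichment(target, bg, memb)
  expect_equal(nrow(res), 2)  # empty set skipped
  hit <- res[res$set_id == "hit", ]
  expect_equal(hit$p_value, oracle_hyper_tail(6, 10, 60, 12), tolerance = 1e-12)
  ft <- fisher.test(matrix(c(6, 4, 6, 44), 2), alternative = "greater")
  expect_equal(hit$p_value, ft$p.value, tolerance = 1e-9)
  # target == background: every set has P = 1
  res_all <- set_enrichment(bg, bg, memb)
  expect_true(all(res_all$p_value == 1))
  expect_error(set_enrichment(c(bg[1], "stranger"), bg, memb), "subset")
})

test_that("random targets give calibrated (conservative) enrichment rates", {
  set.seed(91)
  bg <- sprintf("g%03d", 1:200)
  memb <- do.call(rbind, lapply(1:10, function(i)
    data.frame(set_id = paste0("s", i), gene = sample(bg, 25))))
  hits <- vapply(1:50, function(i) {
    res <- set_enrichment(sample(bg, 20), bg, memb, correction = "BH")
    sum(res$p_adjusted < 0.05)
  }, numeric(1))
  expect_lte(mean(hits > 0), 0.1)
})

test_that("the hub test flags high-degree targets and is seed-stable", {
  # star-like fixture: hubs connected to everything plus a sparse periphery
  hubs <- paste0("hub", 1:4)
  periph <- paste0("p", 1:60)
  edges <- rbind(
    expand.grid(gene_a = hubs, gene_b = periph, stringsAsFactors = FALSE),
    data.frame(gene_a = periph[1:59], gene_b = periph[2:60]))
  res <- hub_degree_test(edges, hubs, n_resamples = 999, seed = 17)
  expect_lt(res$p_value, 0.01)
  res_again <- hub_degree_test(edges, hubs, n_resamples = 999, seed = 17)
  expect_identical(res$p_value, res_again$p_value)
  expect_error(hub_degree_test(edges, c(hubs, periph, "extra"), seed = 1),
               "absent|more target")
})

test_that("cross-species convergence counts multiplicity and planted families", {
  # disjoint sets: all multiplicities 1
  res0 <- cross_species_convergence(list(a = c("g1", "g2"), b = c("g3")))
  expect_true(all(res0$multiplicity$n_species == 1))
  # one gene common to 3 species
  res1 <- cross_species_convergence(list(a = c("g1", "g2"), b = c("g1"),
                                         c = c("g1", "g9")))
  expect_equal(res1$multiplicity$n_species[res1$multiplicity$gene == "g1"], 3L)
  expect_equal(res1$shared_genes, "g1")
  # planted family shared by 4 of 7 species is recovered with adjusted P < 0.05
  set.seed(95)
  bg <- sprintf("o%03d", 1:300)
  fam <- bg[1:10]
  memb <- rbind(data.frame(set_id = "famX", gene = fam),
                do.call(rbind, lapply(1:12, function(i)
                  data.frame(set_id = paste0("f", i), gene = sample(bg[11:300], 12)))))
  psgs <- lapply(1:7, function(i) {
    base <- sample(bg[11:300], 8)
    if (i <= 4) c(base, sample(fam, 2)) else base
  })
  names(psgs) <- paste0("sp", 1:7)
  res2 <- cross_species_convergence(psgs, membership = memb, background = bg,
                                    min_species = 4)
  expect_true("famX" %in% res2$set_sharing$set_id[res2$set_sharing$n_species >= 4])
  famP <- res2$enrichment[res2$enrichment$set_id == "famX", ]
  expect_lt(famP$p_adjusted, 0.05)
  # orthology mapping reports unmapped ids
  orth <- data.frame(gene = c("g1", "g2"), ortholog = c("OG1", "OG2"))
  res3 <- cross_species_convergence(list(a = c("g1", "gX")), orthology = orth)
  expect_equal(res3$unmapped, "gX")
})
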