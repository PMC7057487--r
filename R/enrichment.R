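#' Deleterious-variant burden test
#'
#' Contrasts deleterious (rejected-substitution score > `rs_threshold`)
#' versus benign derived-allele counts between the wild and domestic cohorts
#' with a chi-square test on the 2x2 table, and reports the per-cohort mean
#' derived allele frequency of the deleterious sites. An empty table class
#' falls back to Fisher's exact test (logged in the result).
#'
#' @param scores data.frame with `pos` and `rs` for the scored
#'   (nonsynonymous) sites.
#' @param gt a [genotype_table()] containing both cohorts.
#' @param ancestral per-site coding (`"ref"`/`"alt"`/`NA`).
#' @param wild,domestic population labels.
#' @param rs_threshold deleterious threshold on the RS score (default 2).
#' @param unit `"alleles"` (default: derived allele counts fill the table)
#'   or `"sites"` (count sites segregating for a derived allele per cohort).
#' @return list with the 2x2 `table`, `chisq`, `p_value`, `test` used,
#'   `prop_deleterious` and `mean_derived_freq` per cohort.
#' @export
deleterious_burden_test <- function(scores, gt, ancestral, wild = "wild",
                                    domestic = "domestic", rs_threshold = 2,
                                    unit = c("alleles", "sites")) {
  unit <- match.arg(unit)
  idx <- match(scores$pos, gt$positions)
  ok <- !is.na(idx) & !is.na(ancestral[idx])
  scores <- scores[ok, , drop = FALSE]
  idx <- idx[ok]
  deleterious <- scores$rs > rs_threshold
  cohort_counts <- function(pop) {
    ac <- site_allele_counts(gt, pop)[idx, , drop = FALSE]
    der <- ifelse(ancestral[idx] == "ref", ac$n_alt, ac$n_chr - ac$n_alt)
    freq <- ifelse(ac$n_chr > 0, der / ac$n_chr, NA_real_)
    if (unit == "alleles") {
      c(del = sum(der[deleterious]), ben = sum(der[!deleterious]),
        mean_freq = mean(freq[deleterious], na.rm = TRUE))
    } else {
      c(del = sum(der[deleterious] > 0), ben = sum(der[!deleterious] > 0),
        mean_freq = mean(freq[deleterious], na.rm = TRUE))
    }
  }
  w <- cohort_counts(wild); d <- cohort_counts(domestic)
  tab <- matrix(c(d["del"], d["ben"], w["del"], w["ben"]), nrow = 2,
                dimnames = list(c("deleterious", "benign"), c("domestic", "wild")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    p <- fisher.test(tab)$p.value
    chisq <- NA_real_
    test <- "fisher-fallback"
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    chisq <- unname(ct$statistic); p <- ct$p.value
    test <- "chi-square"
  }
  list(table = tab, chisq = chisq, p_value = p, test = test,
       prop_deleterious = c(wild = unname(w["del"] / (w["del"] + w["ben"])),
                            domestic = unname(d["del"] / (d["del"] + d["ben"]))),
       mean_derived_freq = c(wild = unname(w["mean_freq"]),
                             domestic = unname(d["mean_freq"])),
       n_deleterious_sites = sum(deleterious))
}

#' Genomic-region enrichment of putatively adaptive SNPs
#'
#' Putatively adaptive mutations (sweep SNPs with extreme negative iHS) are
#' tested for enrichment in each of the eight region categories: the
#' expected count per region is the total count times the region's bp
#' fraction of the sweep territory; each region gets a goodness-of-fit
#' chi-square of observed versus expected (region against complement),
#' Bonferroni-corrected over the regions.
#'
#' @param adaptive data.frame with `chrom`, `pos` of the adaptive SNPs.
#' @param index an [annotation_index()].
#' @param territory sweep intervals (`chrom`, `start`, `end`) over which the
#'   region fractions are computed.
#' @return data.frame per region: `region`, `fraction`, `observed`,
#'   `expected`, `chisq`, `p_value`, `p_adjusted` (Bonferroni).
#' @export
region_enrichment <- function(adaptive, index, territory) {
  frac <- region_fractions(index, territory)
  cls <- classify_positions(index, adaptive$chrom, adaptive$pos)
  total <- nrow(adaptive)
  obs <- vapply(names(frac), function(ct) sum(cls == ct), numeric(1))
  bad <- frac == 0 & obs > 0
  if (any(bad))
    stop("adaptive SNPs observed in zero-fraction region: ",
         paste(names(frac)[bad], collapse = ","), " (annotation inconsistency)")
  res <- data.frame(region = names(frac), fraction = unname(frac),
                    observed = unname(obs), expected = total * unname(frac),
                    chisq = NA_real_, p_value = NA_real_, test = "chi-square",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res))) {
    f <- res$fraction[i]
    if (f == 0 || f == 1 || total == 0) { res$chisq[i] <- 0; res$p_value[i] <- 1; next }
    ct <- suppressWarnings(chisq.test(c(res$observed[i], total - res$observed[i]),
                                      p = c(f, 1 - f)))
    res$chisq[i] <- unname(ct$statistic)
    if (min(total * f, total * (1 - f)) < 5) {
      # the chi-square approximation breaks down for rare categories;
      # fall back to the exact binomial test
      res$p_value[i] <- stats::binom.test(res$observed[i], total, f)$p.value
      res$test[i] <- "exact-binomial"
    } else {
      res$p_value[i] <- ct$p.value
    }
  }
  res$p_adjusted <- p.adjust(res$p_value, method = "bonferroni")
  res
}

#' Gene-set enrichment by one-sided Fisher test
#'
#' For every set, the 2x2 table (in set x in target, over the background) is
#' tested for over-representation; the one-sided Fisher P equals the
#' hypergeometric upper tail and is computed as such. Used uniformly for
#' gene families, pathways, trait-association tables and cross-species
#' shared-family tests.
#'
#' @param target character vector of target genes (must be a subset of
#'   `background`).
#' @param background character vector of background genes.
#' @param membership data.frame with `set_id`, `gene`.
#' @param correction `"BH"` (default) or `"bonferroni"`.
#' @return data.frame per set: `set_id`, `n_set`, `n_target_in_set`,
#'   `expected`, `odds_ratio`, `p_value`, `p_adjusted`. Sets with no member
#'   in the background are skipped.
#' @export
set_enrichment <- function(target, background, membership,
                           correction = c("BH", "bonferroni")) {
  correction <- match.arg(correction)
  target <- unique(target); background <- unique(background)
  if (!all(target %in% background))
    stop("target genes must be a subset of the background")
  N <- length(background); K <- length(target)
  sets <- unique(membership$set_id)
  rows <- lapply(sets, function(s) {
    genes <- intersect(membership$gene[membership$set_id == s], background)
    n <- length(genes)
    if (n == 0) return(NULL)  # empty in background: skipped
    a <- length(intersect(genes, target))
    # one-sided Fisher: P(X >= a), X ~ Hypergeometric(K draws from n/N-n)
    p <- phyper(a - 1, n, N - n, K, lower.tail = FALSE)
    exp_a <- K * n / N
    or <- (a * (N - n - K + a)) / max(1e-300, (n - a) * (K - a))
    data.frame(set_id = s, n_set = n, n_target_in_set = a, expected = exp_a,
               odds_ratio = or, p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(data.frame(set_id = character(0), n_set = integer(0),
                                      n_target_in_set = integer(0), expected = numeric(0),
                                      odds_ratio = numeric(0), p_value = numeric(0),
                                      p_adjusted = numeric(0)))
  res$p_adjusted <- p.adjust(res$p_value, method = correction)
  res
}
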