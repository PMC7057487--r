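#' Prune SNPs in strong linkage disequilibrium
#'
#' Sliding-window LD pruning on haplotype allele correlations: within each
#' 100-SNP window (stepped by 20 SNPs) sites with squared correlation above
#' `r2_max` with an already-retained neighbour are excluded. The greedy scan
#' keeps the earlier site of an offending pair, so the result is deterministic
#' for a fixed input order and within every evaluated window no retained pair
#' has r-squared above the threshold.
#'
#' @param gt a [genotype_table()].
#' @param window_snps window width in SNPs (default 100).
#' @param step_snps step in SNPs (default 20).
#' @param r2_max maximum tolerated squared correlation (default 0.1).
#' @return list with `keep` (sorted integer indices of retained sites) and
#'   `n_monomorphic` (sites with undefined r-squared, treated as unlinked and
#'   retained).
#' @export
ld_prune <- function(gt, window_snps = 100, step_snps = 20, r2_max = 0.1) {
  m <- n_sites(gt)
  if (m < 2) stop("ld_prune requires at least 2 sites")
  h <- gt$haplotypes
  mono <- apply(h, 2, function(x) {
    x <- x[!is.na(x)]
    length(unique(x)) < 2L
  })
  kept <- rep(TRUE, m)
  starts <- unique(c(seq(1L, max(1L, m - window_snps + 1L), by = step_snps),
                     max(1L, m - window_snps + 1L)))
  for (s in starts) {
    idx <- s:min(s + window_snps - 1L, m)
    idx <- idx[kept[idx] & !mono[idx]]
    if (length(idx) < 2L) next
    r2 <- suppressWarnings(cor(h[, idx, drop = FALSE],
                               use = "pairwise.complete.obs"))^2
    r2[is.na(r2)] <- 0
    for (a in seq_along(idx)) {
      if (!kept[idx[a]]) next
      for (b in seq_along(idx)) {
        if (b <= a || !kept[idx[b]]) next
        if (r2[a, b] > r2_max) kept[idx[b]] <- FALSE
      }
    }
  }
  list(keep = which(kept), n_monomorphic = sum(mono))
}
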