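#' Per-SNP f4 products and their mean
#'
#' `f4(A, B; C, D)` is the mean over SNPs of `(pA - pB) * (pC - pD)` on a
#' shared allele orientation. Under a strict population tree its expectation
#' is 0; systematic departures indicate gene flow.
#'
#' @param freqs data.frame with columns `pA`, `pB`, `pC`, `pD` (allele
#'   frequencies per SNP, shared orientation). Rows with any missing
#'   frequency are dropped.
#' @return list with `f4` (the mean), `products` (per retained SNP) and
#'   `n_snps`.
#' @export
f4_statistic <- function(freqs) {
  keep <- complete.cases(freqs[, c("pA", "pB", "pC", "pD")])
  f <- freqs[keep, , drop = FALSE]
  if (nrow(f) == 0) stop("no SNPs with frequencies in all four populations")
  products <- (f$pA - f$pB) * (f$pC - f$pD)
  list(f4 = mean(products), products = products, n_snps = length(products))
}

#' Four-population test with block-jackknife Z score
#'
#' The standard error of f4 is estimated by a delete-one block jackknife
#' over consecutive blocks of `block_size_snps` genome-ordered SNPs; the
#' Z score `f4 / SE` is approximately standard normal under the null of no
#' gene flow. `Z > z_crit` indicates gene flow between A and C or between B
#' and D; `Z < -z_crit` between A and D or between B and C.
#'
#' @param products per-SNP f4 products in genome order (from
#'   [f4_statistic()]).
#' @param block_size_snps SNPs per jackknife block (default 100000; scale
#'   down for small datasets). A trailing remainder shorter than half a
#'   block is merged into the last block.
#' @param z_crit significance threshold on |Z| (default 4).
#' @return list of class `f4_result`: `f4`, `se`, `z`, `n_blocks`, `n_snps`,
#'   `interpretation`, `degenerate` (TRUE when the jackknife SE collapsed to
#'   zero and was floored).
#' @export
f4_ztest <- function(products, block_size_snps = 100000, z_crit = 4) {
  n <- length(products)
  block <- pmin(floor((seq_len(n) - 1) / block_size_snps) + 1, max(1, n %/% block_size_snps + (n %% block_size_snps > 0)))
  # merge a short trailing remainder (< half block) into the previous block
  m <- max(block)
  if (m >= 2 && sum(block == m) < block_size_snps / 2) {
    block[block == m] <- m - 1L
    m <- m - 1L
  }
  if (m < 2) stop("only one jackknife block; reduce block_size_snps")
  f4 <- mean(products)
  total <- sum(products)
  loo <- vapply(seq_len(m), function(b) {
    nb <- sum(block == b)
    (total - sum(products[block == b])) / (n - nb)
  }, numeric(1))
  se <- sqrt((m - 1) / m * sum((loo - mean(loo))^2))
  degenerate <- FALSE
  if (se <= .Machine$double.eps) {
    degenerate <- TRUE
    se <- .Machine$double.eps
  }
  z <- f4 / se
  interp <- if (z > z_crit) "A-C or B-D" else if (z < -z_crit) "A-D or B-C" else "none"
  structure(list(f4 = f4, se = se, z = z, n_blocks = m, n_snps = n,
                 interpretation = interp, degenerate = degenerate),
            class = "f4_result")
}

#' @export
print.f4_result <- function(x, ...) {
  cat(sprintf("f4 = %.6g  SE = %.6g  Z = %.3f  (%d SNPs, %d blocks)\n",
              x$f4, x$se, x$z, x$n_snps, x$n_blocks))
  cat("interpretation:", x$interpretation, if (x$degenerate) "[degenerate SE]" else "", "\n")
  invisible(x)
}

#' f4 test straight from a genotype table
#'
#' Computes alternate-allele frequencies for four populations (shared
#' orientation by construction) and runs [f4_statistic()] +
#' [f4_ztest()].
#'
#' @param gt a [genotype_table()] containing the four populations.
#' @param pops character vector of length 4: populations A, B, C, D.
#' @param block_size_snps,z_crit passed to [f4_ztest()].
#' @return an `f4_result`.
#' @export
f4_from_gt <- function(gt, pops, block_size_snps = 100000, z_crit = 4) {
  stopifnot(length(pops) == 4)
  fr <- lapply(pops, function(p) {
    ac <- site_allele_counts(gt, p)
    ifelse(ac$n_chr > 0, ac$n_alt / ac$n_chr, NA_real_)
  })
  freqs <- data.frame(pA = fr[[1]], pB = fr[[2]], pC = fr[[3]], pD = fr[[4]])
  ord <- order(gt$chrom, gt$positions)
  freqs <- freqs[ord, , drop = FALSE]
  fs <- f4_statistic(freqs)
  f4_ztest(fs$products, block_size_snps = block_size_snps, z_crit = z_crit)
}
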