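#' Population SNP density
#'
#' Genetic diversity summarised as the number of sites segregating within a
#' population normalised by the genome size.
#'
#' @param gt a [genotype_table()].
#' @param population population label (`NULL` for all samples).
#' @param genome_size genome size in bp.
#' @return fraction of segregating sites per bp.
#' @export
pop_snp_density <- function(gt, population = NULL, genome_size) {
  if (genome_size <= 0) stop("genome_size must be positive")
  ac <- site_allele_counts(gt, population)
  seg <- ac$n_alt > 0 & ac$n_alt < ac$n_chr & ac$n_chr > 0
  sum(seg) / genome_size
}

#' Pooled heterozygosity (Hp) per window
#'
#' Per window, the major and minor allele counts of the contained SNPs are
#' summed and combined as
#' `Hp = 2 * sum(n_max) * sum(n_min) / (sum(n_max) + sum(n_min))^2`,
#' which lies in \[0, 0.5\]. Windows without SNPs are flagged missing.
#'
#' @param gt a [genotype_table()].
#' @param windows window tiling from [make_windows()].
#' @param population optional population label.
#' @param segregating_only drop sites monomorphic within the population
#'   before summing (default FALSE: all table sites contribute, so fixation
#'   inside a sweep drags Hp down).
#' @return data.frame per window: `chrom`, `start`, `end`, `snp_count`,
#'   `sum_nmax`, `sum_nmin`, `hp`.
#' @export
window_hp <- function(gt, windows, population = NULL, segregating_only = FALSE) {
  ac <- site_allele_counts(gt, population)
  n_ref <- ac$n_chr - ac$n_alt
  nmax <- pmax(ac$n_alt, n_ref)
  nmin <- pmin(ac$n_alt, n_ref)
  use <- ac$n_chr > 0
  if (segregating_only) use <- use & nmin > 0
  out <- windows
  out$snp_count <- 0L; out$sum_nmax <- 0; out$sum_nmin <- 0; out$hp <- NA_real_
  for (i in seq_len(nrow(windows))) {
    inw <- use & sites_in_window(gt, windows$chrom[i], windows$start[i], windows$end[i])
    out$snp_count[i] <- sum(inw)
    if (!any(inw)) next
    smax <- sum(nmax[inw]); smin <- sum(nmin[inw])
    out$sum_nmax[i] <- smax; out$sum_nmin[i] <- smin
    out$hp[i] <- hp_from_sums(smax, smin)
  }
  out
}

#' Hp from summed major/minor allele counts
#' @param sum_nmax,sum_nmin summed major and minor allele counts
#' @return the pooled heterozygosity statistic
#' @export
hp_from_sums <- function(sum_nmax, sum_nmin) {
  tot <- sum_nmax + sum_nmin
  ifelse(tot > 0, 2 * sum_nmax * sum_nmin / tot^2, NA_real_)
}

#' Unfolded site frequency spectrum of a window
#'
#' Tallies `S_i`, the number of derived variants found `i` times among the
#' `n` sampled chromosomes, for the polarizable segregating sites of a
#' window. Sites with unknown ancestral allele or any missing call are
#' skipped and counted.
#'
#' @param gt a [genotype_table()].
#' @param window single-row window (`chrom`, `start`, `end`), or `NULL` for
#'   all sites.
#' @param ancestral character vector per site: `"ref"`, `"alt"` or `NA`
#'   (unpolarizable).
#' @param population optional population label.
#' @return list with `S_i` (length `n - 1`), `n`, `S`, and `skipped`.
#' @export
unfolded_window_sfs <- function(gt, window = NULL, ancestral, population = NULL) {
  rows <- pop_rows(gt, population)
  n <- length(rows)
  sel <- if (is.null(window)) rep(TRUE, n_sites(gt)) else
    sites_in_window(gt, window$chrom[1], window$start[1], window$end[1])
  idx <- which(sel)
  h <- gt$haplotypes[rows, idx, drop = FALSE]
  anc <- ancestral[idx]
  complete <- colSums(is.na(h)) == 0L
  polar <- !is.na(anc)
  usable <- complete & polar
  alt_cnt <- colSums(h[, usable, drop = FALSE])
  der <- ifelse(anc[usable] == "ref", alt_cnt, n - alt_cnt)
  seg <- der > 0 & der < n
  S_i <- if (any(seg)) tabulate(as.integer(der[seg]), nbins = n - 1L) else
    integer(n - 1L)
  list(S_i = S_i, n = n, S = sum(S_i), skipped = sum(!usable))
}

#' Tajima (1989) variance constants
#' @param n number of chromosomes (>= 2)
#' @return named list `a1, a2, b1, b2, c1, c2, e1, e2`
#' @export
tajima_constants <- function(n) {
  if (n < 2) stop("n must be >= 2")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Theta estimators from an unfolded SFS
#'
#' `theta_pi` (mean pairwise heterozygosity), `theta_w` (Watterson, from the
#' segregating-site count) and `theta_h` (weighted toward high-frequency
#' derived alleles).
#'
#' @param sfs result of [unfolded_window_sfs()].
#' @return list `theta_pi`, `theta_w`, `theta_h`, `theta_l`, plus `n`, `S`.
#' @export
theta_set <- function(sfs) {
  n <- sfs$n; S_i <- sfs$S_i; i <- seq_len(n - 1)
  k <- tajima_constants(n)
  list(theta_pi = sum(2 * S_i * i * (n - i)) / (n * (n - 1)),
       theta_w = sfs$S / k$a1,
       theta_h = sum(2 * S_i * i^2) / (n * (n - 1)),
       theta_l = sum(S_i * i) / (n - 1),
       n = n, S = sfs$S)
}

#' Tajima's D
#'
#' `(theta_pi - theta_w) / sqrt(e1*S + e2*S*(S-1))` with the Tajima (1989)
#' constants. Windows with no segregating sites return `NA` (missing), not 0.
#'
#' @param sfs result of [unfolded_window_sfs()] (the statistic only uses the
#'   folded information, so polarization does not affect it).
#' @param min_n minimum sample size (default 4).
#' @return Tajima's D, or `NA` when `S = 0`.
#' @export
tajimas_d <- function(sfs, min_n = 4) {
  if (sfs$n < 2) stop("n must be >= 2")
  if (sfs$n < min_n) return(NA_real_)
  if (sfs$S == 0) return(NA_real_)
  th <- theta_set(sfs)
  k <- tajima_constants(sfs$n)
  v <- k$e1 * sfs$S + k$e2 * sfs$S * (sfs$S - 1)
  if (v <= 0) return(NA_real_)
  (th$theta_pi - th$theta_w) / sqrt(v)
}

#' Fay & Wu's H (normalized)
#'
#' Numerator `theta_pi - theta_h`; an excess of high-frequency derived
#' alleles, the footprint of a sweep, makes it negative. The variance of
#' `theta_pi - theta_l` follows Zeng et al. (2006); since
#' `theta_pi - theta_h = 2 (theta_pi - theta_l)`, the normalized statistic is
#' the numerator over twice that standard deviation.
#'
#' @inheritParams tajimas_d
#' @return normalized H, or `NA` when `S = 0`.
#' @export
fay_wu_h <- function(sfs, min_n = 4) {
  if (sfs$n < 2) stop("n must be >= 2")
  if (sfs$n < min_n) return(NA_real_)
  if (sfs$S == 0) return(NA_real_)
  n <- sfs$n
  th <- theta_set(sfs)
  k <- tajima_constants(n)
  bn1 <- sum(1 / seq_len(n)^2)  # sum_{i=1}^{n} 1/i^2
  theta <- th$theta_w
  theta2 <- sfs$S * (sfs$S - 1) / (k$a1^2 + k$a2)
  v <- (n - 2) / (6 * (n - 1)) * theta +
    (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
    (9 * n * (n - 1)^2) * theta2
  if (v <= 0) return(NA_real_)
  (th$theta_pi - th$theta_h) / (2 * sqrt(v))
}

#' Window scan of SFS statistics
#'
#' Computes per-window theta estimators, Tajima's D and Fay & Wu's H for one
#' population. Windows with fewer than `min_snps` polarizable SNPs are
#' reported missing.
#'
#' @param gt a [genotype_table()].
#' @param windows tiling from [make_windows()].
#' @param ancestral per-site ancestral coding (`"ref"`/`"alt"`/`NA`).
#' @param population optional population label.
#' @param min_snps minimum SNPs per window (default 2).
#' @return data.frame per window with `snp_count`, `theta_pi`, `theta_w`,
#'   `theta_h`, `tajima_d`, `fay_wu_h`.
#' @export
sfs_scan_windows <- function(gt, windows, ancestral, population = NULL,
                             min_snps = 2) {
  out <- windows
  out$snp_count <- 0L
  out$theta_pi <- out$theta_w <- out$theta_h <- NA_real_
  out$tajima_d <- out$fay_wu_h <- NA_real_
  for (i in seq_len(nrow(windows))) {
    sfs <- unfolded_window_sfs(gt, windows[i, , drop = FALSE], ancestral, population)
    out$snp_count[i] <- sfs$S
    if (sfs$S < min_snps) next
    th <- theta_set(sfs)
    out$theta_pi[i] <- th$theta_pi
    out$theta_w[i] <- th$theta_w
    out$theta_h[i] <- th$theta_h
    out$tajima_d[i] <- tajimas_d(sfs)
    out$fay_wu_h[i] <- fay_wu_h(sfs)
  }
  out
}
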