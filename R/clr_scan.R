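#' Probability of escaping a sweep
#'
#' A lineage at distance `d` bp from a selected site escapes the sweep with
#' probability `1 - exp(-alpha * d)`, where `alpha = r * ln(2N) / s` combines
#' recombination rate, population size and selection coefficient. The scan
#' only considers sites with `alpha * d <= 12`, at which the escape
#' probability is 0.999994.
#'
#' @param alpha compound sweep-strength parameter per bp.
#' @param d distance to the selected site in bp.
#' @return escape probability in \[0, 1).
#' @export
escape_probability <- function(alpha, d) 1 - exp(-alpha * d)

#' Background (genome-wide) unfolded SFS
#'
#' Normalized frequency distribution of derived allele counts `1..n-1` over
#' all polarizable segregating sites, with one pseudo-count added to every
#' class so that no outcome has zero likelihood on small cohorts.
#'
#' @param gt a [genotype_table()].
#' @param ancestral per-site ancestral coding (`"ref"`/`"alt"`/`NA`).
#' @param population optional population label.
#' @param pseudo_count smoothing count per class (default 1).
#' @return list with `p` (probabilities over counts 1..n-1, summing to 1),
#'   `n`, and the raw `counts`.
#' @export
background_sfs <- function(gt, ancestral, population = NULL, pseudo_count = 1) {
  sfs <- unfolded_window_sfs(gt, NULL, ancestral, population)
  if (sfs$S == 0) stop("no polarizable segregating sites for the background SFS")
  counts <- sfs$S_i
  p <- counts + pseudo_count
  list(p = p / sum(p), n = sfs$n, counts = counts)
}

#' Site probability under the sweep model
#'
#' Lineage-escape approximation of the post-sweep SFS: the background derived
#' count `jb` is drawn from `B`; each of the `n` lineages independently
#' escapes the sweep with probability `p_e`; escaped lineages retain their
#' original allele (a hypergeometric draw of derived alleles among the
#' escapees), while non-escaped lineages coalesce onto the swept,
#' ancestral-carrying haplotype. The distribution is renormalized over
#' segregating outcomes `j = 1..n-1`. At `p_e = 1` the model collapses to the
#' background SFS exactly.
#'
#' @param j derived count (scalar or vector in 1..n-1); `NULL` returns the
#'   full distribution.
#' @param n number of chromosomes.
#' @param p_e escape probability.
#' @param B background SFS from [background_sfs()] (its `p` is used), or a
#'   bare probability vector over 1..n-1.
#' @return probability (or vector over `j = 1..n-1` when `j` is `NULL`).
#' @export
sweep_site_probability <- function(j = NULL, n, p_e, B) {
  p <- if (is.list(B)) B$p else B
  stopifnot(length(p) == n - 1)
  unnorm <- numeric(n - 1)
  e_probs <- dbinom(0:n, n, p_e)
  for (jb in seq_len(n - 1)) {
    # escapees are a uniform subset; derived among e escapees ~ hypergeometric
    for (e in 0:n) {
      if (e_probs[e + 1] == 0) next
      jj <- seq_len(min(e, n - 1))
      if (length(jj) == 0) next
      unnorm[jj] <- unnorm[jj] + p[jb] * e_probs[e + 1] * dhyper(jj, jb, n - jb, e)
    }
  }
  tot <- sum(unnorm)
  out <- if (tot > 0) unnorm / tot else c(1, rep(0, n - 2))  # p_e -> 0 limit: singleton
  if (is.null(j)) out else out[j]
}

# log sweep-site probability lookup on a uniform alpha*d grid in [0, cutoff]
# (uniform in alpha*d resolves p_e exponentially finely near 1, where the
# model must converge to the background so that distant sites contribute ~0)
sweep_prob_table <- function(n, B, cutoff = 12, n_nodes = 481) {
  ad_grid <- seq(0, cutoff, length.out = n_nodes)
  pe_grid <- 1 - exp(-ad_grid)
  m <- vapply(pe_grid, function(pe) sweep_site_probability(NULL, n, pe, B),
              numeric(n - 1))
  # floor keeps the log finite; impossible outcomes still reject an alpha
  list(logp = log(pmax(m, 1e-12)), ad_grid = ad_grid,
       step = ad_grid[2] - ad_grid[1], n_nodes = n_nodes)
}

# interpolated log probability for derived counts j at alpha*d values ad
sweep_logp_interp <- function(tab, j, ad) {
  t <- pmin(pmax(ad / tab$step, 0), tab$n_nodes - 1 - 1e-9)
  lo <- floor(t)
  fr <- t - lo
  l0 <- tab$logp[cbind(j, lo + 1)]
  l1 <- tab$logp[cbind(j, lo + 2)]
  (1 - fr) * l0 + fr * l1
}

#' Composite likelihood ratio scan for selective sweeps
#'
#' At every SNP position the composite log-likelihood of the surrounding
#' derived counts under the sweep model (maximized over a fixed log-spaced
#' `alpha` grid) is contrasted with the background SFS:
#' `CLR = 2 * (max_alpha sum log P_sweep - sum log P_background)`, clipped
#' below at 0. Only sites with `alpha * d <= cutoff` (default 12) enter the
#' composite product; the focal site's own term (distance 0) is excluded.
#'
#' @param gt a [genotype_table()].
#' @param ancestral per-site ancestral coding.
#' @param population optional population label.
#' @param B background SFS; computed from `gt` when `NULL`.
#' @param alpha_grid log-spaced grid of `alpha` values (default 32 points
#'   spanning 1e-7..1e-2 per bp).
#' @param cutoff `alpha * d` truncation (default 12).
#' @param n_nodes resolution of the `alpha * d` lookup grid (default 481;
#'   values between nodes are linearly interpolated).
#' @param chunk positions per vectorised block (memory control).
#' @return data.frame per segregating site: `chrom`, `pos`, `clr`,
#'   `alpha_hat`.
#' @export
clr_scan <- function(gt, ancestral, population = NULL, B = NULL,
                     alpha_grid = exp(seq(log(1e-7), log(1e-2), length.out = 32)),
                     cutoff = 12, n_nodes = 481, chunk = 512L) {
  rows <- pop_rows(gt, population)
  n <- length(rows)
  if (is.null(B)) B <- background_sfs(gt, ancestral, population)
  h <- gt$haplotypes[rows, , drop = FALSE]
  complete <- colSums(is.na(h)) == 0L
  polar <- !is.na(ancestral)
  alt_cnt <- colSums(h, na.rm = TRUE)
  der <- ifelse(ancestral == "ref", alt_cnt, n - alt_cnt)
  usable <- complete & polar & der > 0 & der < n
  idx <- which(usable)
  pos <- gt$positions[idx]
  chromv <- gt$chrom[idx]
  j_obs <- der[idx]
  logB <- log(B$p)
  tab <- sweep_prob_table(n, B, cutoff = cutoff, n_nodes = n_nodes)
  out <- data.frame(chrom = chromv, pos = pos, clr = 0, alpha_hat = NA_real_,
                    stringsAsFactors = FALSE)
  for (ctg in unique(chromv)) {
    cs <- which(chromv == ctg)
    cpos <- pos[cs]; cj <- j_obs[cs]
    clogB <- logB[cj]
    m <- length(cs)
    for (blk_start in seq(1L, m, by = chunk)) {
      blk <- blk_start:min(blk_start + chunk - 1L, m)
      D <- abs(outer(cpos[blk], cpos, "-"))  # focal x site distances
      best_ll <- rep(-Inf, length(blk))
      best_a <- rep(NA_real_, length(blk))
      logB_mat <- matrix(clogB, nrow = length(blk), ncol = m, byrow = TRUE)
      j_mat <- rep(cj, each = length(blk))
      for (a in alpha_grid) {
        ad <- a * D
        incl <- ad <= cutoff & D > 0
        lp <- matrix(sweep_logp_interp(tab, j_mat, as.vector(ad)),
                     nrow = length(blk))
        contrib <- lp - logB_mat
        contrib[!incl] <- 0
        ll <- rowSums(contrib)
        upd <- ll > best_ll
        best_ll[upd] <- ll[upd]
        best_a[upd] <- a
      }
      out$clr[cs[blk]] <- pmax(0, 2 * best_ll)
      out$alpha_hat[cs[blk]] <- best_a
    }
  }
  out
}

#' Maximum CLR per window
#'
#' @param scan output of [clr_scan()].
#' @param windows window tiling.
#' @return data.frame per window with `n_snps` and `clr_max` (missing for
#'   empty windows).
#' @export
clr_windows <- function(scan, windows) {
  out <- windows
  out$n_snps <- 0L
  out$clr_max <- NA_real_
  for (i in seq_len(nrow(windows))) {
    inw <- scan$chrom == windows$chrom[i] &
      (scan$pos - 1) >= windows$start[i] & (scan$pos - 1) < windows$end[i]
    out$n_snps[i] <- sum(inw)
    if (any(inw)) out$clr_max[i] <- max(scan$clr[inw])
  }
  out
}
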