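# Independent brute-force oracles. These deliberately re-derive each quantity
# from first principles, sharing no code with the implementation paths they
# check.

# mean pairwise difference per site-set between haplotype rows
oracle_pairwise_pi <- function(h) {
  n <- nrow(h)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(h[i, ] != h[j, ])
  tot / choose(n, 2)
}

# Tajima (1989) D written out independently
oracle_tajima_d <- function(S_i, n) {
  S <- sum(S_i)
  if (S == 0) return(NA_real_)
  i <- seq_len(n - 1)
  pi_hat <- sum(2 * S_i * i * (n - i)) / (n * (n - 1))
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  w_hat <- S / a1
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  v <- (c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1)
  (pi_hat - w_hat) / sqrt(v)
}

# one-sided Fisher/hypergeometric upper tail P(X >= a) from binomial
# coefficients only
oracle_hyper_tail <- function(a, n_set, N, K) {
  jj <- max(a, max(0, n_set + K - N)):min(n_set, K)
  sum(choose(n_set, jj) * choose(N - n_set, K - jj)) / choose(N, K)
}

# sweep-model site distribution by exhaustive enumeration over all escape
# configurations and all placements of the background derived alleles
oracle_sweep_prob <- function(n, p_e, B) {
  unnorm <- numeric(n - 1)
  for (jb in seq_len(n - 1)) {
    placements <- combn(n, jb)
    p_place <- B[jb] / ncol(placements)
    for (esc_mask in 0:(2^n - 1)) {
      esc <- as.logical(bitwAnd(esc_mask, 2^(0:(n - 1))))
      p_esc <- prod(ifelse(esc, p_e, 1 - p_e))
      if (p_esc == 0) next
      for (k in seq_len(ncol(placements))) {
        j <- sum(placements[, k] %in% which(esc))  # derived alleles that escaped
        if (j >= 1 && j <= n - 1)
          unnorm[j] <- unnorm[j] + p_place * p_esc
      }
    }
  }
  unnorm / sum(unnorm)
}

# delete-one-block jackknife SE recomputed naively
oracle_jackknife_se <- function(products, block_id) {
  ids <- unique(block_id)
  m <- length(ids)
  loo <- vapply(ids, function(b) mean(products[block_id != b]), numeric(1))
  sqrt((m - 1) / m * sum((loo - mean(loo))^2))
}

# all-pairs greedy LD pruning within a single window
oracle_ld_keep <- function(h, r2_max = 0.1) {
  m <- ncol(h)
  keep <- rep(TRUE, m)
  for (a in seq_len(m - 1)) {
    if (!keep[a]) next
    for (b in (a + 1):m) {
      if (!keep[b]) next
      if (sd(h[, a]) == 0 || sd(h[, b]) == 0) next
      if (cor(h[, a], h[, b])^2 > r2_max) keep[b] <- FALSE
    }
  }
  which(keep)
}

# trapezoid integral of an EHH curve truncated at the cutoff crossing
oracle_trapezoid <- function(d, e, cutoff = 0.05) {
  area <- 0
  for (k in seq_along(d)[-1]) {
    if (e[k] >= cutoff) {
      area <- area + (e[k - 1] + e[k]) / 2 * (d[k] - d[k - 1])
    } else {
      x <- d[k - 1] + (e[k - 1] - cutoff) / (e[k - 1] - e[k]) * (d[k] - d[k - 1])
      area <- area + (e[k - 1] + cutoff) / 2 * (x - d[k - 1])
      break
    }
  }
  area
}
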