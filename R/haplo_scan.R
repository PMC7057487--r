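#' Extended haplotype homozygosity decay curve
#'
#' Starting from the carriers of one allele at a core SNP, haplotypes are
#' extended marker by marker in one direction; at each marker the curve
#' records the probability that two randomly drawn carriers are identical
#' over the extended segment: `EHH(x) = sum_i C(k_i, 2) / C(k, 2)` over
#' identity groups of sizes `k_i`. `EHH(0) = 1` and the curve is
#' non-increasing with distance.
#'
#' @param haplotypes complete 0/1 haplotype matrix (rows = chromosomes).
#' @param positions 1-based site positions matching the columns.
#' @param core column index of the core SNP.
#' @param allele 0 or 1: which core allele's carriers to follow.
#' @param direction `"left"` or `"right"` of the core.
#' @param stop_below stop extending once EHH drops below this value (the
#'   first sub-threshold point is kept so the crossing can be interpolated);
#'   default 0 walks to the chromosome end.
#' @return data.frame with `distance` (bp from core) and `ehh`; attribute
#'   `"monomorphic_core"` is TRUE when fewer than 2 carriers exist.
#' @export
ehh_curve <- function(haplotypes, positions, core, allele, direction = c("right", "left"),
                      stop_below = 0) {
  direction <- match.arg(direction)
  carriers <- which(haplotypes[, core] == allele)
  k <- length(carriers)
  if (k < 2) {
    out <- data.frame(distance = 0, ehh = NA_real_)
    attr(out, "monomorphic_core") <- TRUE
    return(out)
  }
  steps <- if (direction == "right") seq_len(ncol(haplotypes) - core) + core else
    rev(seq_len(core - 1))
  dist <- c(0); ehh <- c(1)
  grp <- rep(1L, k)
  denom <- choose(k, 2)
  for (m in steps) {
    a <- haplotypes[carriers, m]
    key <- grp * 2L + a
    grp <- match(key, unique(key))
    e <- sum(choose(tabulate(grp), 2)) / denom
    dist <- c(dist, abs(positions[m] - positions[core]))
    ehh <- c(ehh, e)
    if (e == 0 || e < stop_below) break
  }
  out <- data.frame(distance = dist, ehh = ehh)
  attr(out, "monomorphic_core") <- FALSE
  out
}

#' Integrated EHH (iHH)
#'
#' Trapezoidal integral of an EHH decay curve over physical distance,
#' truncated at the first point where EHH falls below `cutoff` (with linear
#' interpolation to the crossing). If the curve reaches the chromosome end
#' before decaying, the integral is flagged edge-truncated. A list of curves
#' (e.g. both directions) is integrated and summed.
#'
#' @param curve data.frame from [ehh_curve()], or list of such curves.
#' @param cutoff decay cutoff (default 0.05).
#' @return list with `area` and `edge_truncated`.
#' @export
ihh <- function(curve, cutoff = 0.05) {
  if (is.data.frame(curve)) curve <- list(curve)
  area <- 0; edge <- FALSE
  for (cv in curve) {
    if (isTRUE(attr(cv, "monomorphic_core"))) return(list(area = NA_real_, edge_truncated = FALSE))
    d <- cv$distance; e <- cv$ehh
    below <- which(e < cutoff)
    if (length(below) == 0) {
      if (length(d) > 1)
        area <- area + sum(diff(d) * (head(e, -1) + tail(e, -1)) / 2)
      edge <- TRUE
    } else {
      j <- below[1]
      if (j > 1) {
        if (j > 2)
          area <- area + sum(diff(d[1:(j - 1)]) * (e[1:(j - 2)] + e[2:(j - 1)]) / 2)
        # interpolate to the cutoff crossing between points j-1 and j
        x <- d[j - 1] + (e[j - 1] - cutoff) / (e[j - 1] - e[j]) * (d[j] - d[j - 1])
        area <- area + (e[j - 1] + cutoff) / 2 * (x - d[j - 1])
      }
    }
  }
  list(area = area, edge_truncated = edge)
}

#' Per-SNP iHS scores
#'
#' For each core SNP with known ancestral allele and minor allele frequency
#' above `maf_min`, the unstandardized score is `ln(iHH_A / iHH_D)`; it is
#' standardized to mean 0, SD 1 within bins of derived allele frequency so
#' that extreme scores indicate unusually long haplotypes around the derived
#' (iHS < 0) or ancestral (iHS > 0) allele for that frequency class. Sites
#' with any missing call are dropped beforehand.
#'
#' @param gt a [genotype_table()] (phased).
#' @param ancestral per-site ancestral coding (`"ref"`/`"alt"`/`NA`).
#' @param population optional population label.
#' @param maf_min minor allele frequency threshold, exclusive (default 0.05).
#' @param cutoff EHH decay cutoff for iHH (default 0.05).
#' @param bin_width derived-frequency bin width for standardization
#'   (default 0.05).
#' @param min_bin minimum SNPs per bin for standardization (default 20).
#' @param include_edge include edge-truncated cores in standardization and
#'   output (default FALSE; their iHH is biased downward).
#' @return data.frame with one row per analysed site: `site`, `chrom`, `pos`,
#'   `p` (derived frequency), `ihh_a`, `ihh_d`, `raw`, `ihs`, `bin`,
#'   `status` (ok / edge-truncated / monomorphic-core / undefined).
#' @export
ihs_scores <- function(gt, ancestral, population = NULL, maf_min = 0.05,
                       cutoff = 0.05, bin_width = 0.05, min_bin = 20,
                       include_edge = FALSE) {
  rows <- pop_rows(gt, population)
  h <- gt$haplotypes[rows, , drop = FALSE]
  complete <- colSums(is.na(h)) == 0L
  keep <- which(complete)
  h <- h[, keep, drop = FALSE]
  positions <- gt$positions[keep]
  chrom <- gt$chrom[keep]
  anc <- ancestral[keep]
  n <- nrow(h)
  alt_freq <- colMeans(h)
  maf <- pmin(alt_freq, 1 - alt_freq)
  core_ok <- maf > maf_min & !is.na(anc)
  idx <- which(core_ok)
  res <- data.frame(site = keep[idx], chrom = chrom[idx], pos = positions[idx],
                    p = NA_real_, ihh_a = NA_real_, ihh_d = NA_real_,
                    raw = NA_real_, ihs = NA_real_, bin = NA_integer_,
                    status = "ok", stringsAsFactors = FALSE)
  for (r in seq_along(idx)) {
    j <- idx[r]
    der_allele <- if (anc[j] == "ref") 1L else 0L
    p_der <- if (der_allele == 1L) alt_freq[j] else 1 - alt_freq[j]
    res$p[r] <- p_der
    per_allele <- lapply(c(A = 1L - der_allele, D = der_allele), function(al) {
      cl <- ehh_curve(h, positions, j, al, "left", stop_below = cutoff)
      cr <- ehh_curve(h, positions, j, al, "right", stop_below = cutoff)
      if (isTRUE(attr(cl, "monomorphic_core")) || isTRUE(attr(cr, "monomorphic_core")))
        return(NULL)
      ihh(list(cl, cr), cutoff)
    })
    if (is.null(per_allele$A) || is.null(per_allele$D)) {
      res$status[r] <- "monomorphic-core"
      next
    }
    res$ihh_a[r] <- per_allele$A$area
    res$ihh_d[r] <- per_allele$D$area
    if (per_allele$A$edge_truncated || per_allele$D$edge_truncated)
      res$status[r] <- "edge-truncated"
    if (per_allele$D$area == 0 || per_allele$A$area == 0) {
      res$status[r] <- "undefined"
      next
    }
    res$raw[r] <- log(per_allele$A$area / per_allele$D$area)
  }
  res$bin <- as.integer(floor(pmin(res$p, 1 - 1e-12) / bin_width))
  usable <- res$status == "ok" | (include_edge & res$status == "edge-truncated")
  usable <- usable & !is.na(res$raw)
  for (b in unique(res$bin[usable])) {
    inb <- usable & res$bin == b
    if (sum(inb) < min_bin) next
    mu <- mean(res$raw[inb]); sdv <- sd(res$raw[inb])
    if (is.na(sdv) || sdv == 0) next
    res$ihs[inb] <- (res$raw[inb] - mu) / sdv
  }
  res
}

#' Window statistic: proportion of extreme negative iHS
#'
#' @param records output of [ihs_scores()].
#' @param windows window tiling.
#' @param threshold iHS threshold (default -2).
#' @return data.frame per window with `n_defined` and `prop_extreme`
#'   (missing when no defined iHS in the window).
#' @export
ihs_window_stat <- function(records, windows, threshold = -2) {
  def <- records[!is.na(records$ihs), , drop = FALSE]
  out <- windows
  out$n_defined <- 0L
  out$prop_extreme <- NA_real_
  for (i in seq_len(nrow(windows))) {
    inw <- def$chrom == windows$chrom[i] &
      (def$pos - 1) >= windows$start[i] & (def$pos - 1) < windows$end[i]
    out$n_defined[i] <- sum(inw)
    if (any(inw)) out$prop_extreme[i] <- mean(def$ihs[inw] < threshold)
  }
  out
}

#' Empirical window P values within SNP-count bins
#'
#' Windows are binned by their defined-SNP count in increments of
#' `bin_increment`; within a bin the empirical P of a window is the fraction
#' of windows in the bin with a strictly larger statistic (ties do not count
#' as larger). Bins with fewer than `min_windows` windows are removed and
#' their windows get a missing P.
#'
#' @param stats data.frame from [ihs_window_stat()] (columns `n_defined`,
#'   `prop_extreme`), or any data.frame with a count and a statistic column.
#' @param value_col name of the statistic column (default "prop_extreme").
#' @param count_col name of the SNP-count column (default "n_defined").
#' @param bin_increment bin width on the SNP count (default 10).
#' @param min_windows minimum windows per retained bin (default 20).
#' @return the input with columns `count_bin` and `empirical_p` appended.
#' @export
empirical_p_by_bins <- function(stats, value_col = "prop_extreme",
                                count_col = "n_defined", bin_increment = 10,
                                min_windows = 20) {
  v <- stats[[value_col]]
  cnt <- stats[[count_col]]
  stats$count_bin <- ifelse(is.na(v), NA_integer_,
                            as.integer(floor(cnt / bin_increment)))
  stats$empirical_p <- NA_real_
  for (b in unique(stats$count_bin[!is.na(stats$count_bin)])) {
    inb <- which(!is.na(stats$count_bin) & stats$count_bin == b)
    if (length(inb) < min_windows) next
    vb <- v[inb]
    stats$empirical_p[inb] <- vapply(vb, function(x) mean(vb > x), numeric(1))
  }
  stats
}
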