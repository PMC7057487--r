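#' Shuffle-based significance threshold for Hp
#'
#' The genome is summarised as per-1-kb blocks of summed major/minor allele
#' counts. Each shuffle permutes the block order genome-wide (disturbing LD),
#' assembles consecutive blocks into scan windows, computes Hp per window and
#' records the genome-wide minimum. The cutoff is the `rank`-th lowest of the
#' `n_shuffles` minima; rank 50 of 1000 corresponds to a significance level
#' of 0.05.
#'
#' @param blocks data.frame with `sum_nmax`, `sum_nmin` per 1-kb block (e.g.
#'   from [window_hp()] on a 1-kb tiling).
#' @param scan_window_blocks blocks per scan window (e.g. 40 for a 40-kb
#'   window of 1-kb blocks).
#' @param n_shuffles number of shuffles (default 1000).
#' @param rank which lowest minimum becomes the cutoff (default 50).
#' @param seed RNG seed (required for reproducibility).
#' @return list with `cutoff`, the sorted `minima`, and `implied_level`
#'   (`rank / n_shuffles`).
#' @export
hp_shuffle_threshold <- function(blocks, scan_window_blocks, n_shuffles = 1000,
                                 rank = 50, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (n_shuffles < rank) stop("n_shuffles must be >= rank")
  nb <- nrow(blocks)
  if (nb < scan_window_blocks) stop("fewer blocks than one scan window")
  n_groups <- nb %/% scan_window_blocks
  grp <- rep(seq_len(n_groups), each = scan_window_blocks)
  used <- n_groups * scan_window_blocks
  minima <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      perm <- sample.int(nb)
      smax <- blocks$sum_nmax[perm][seq_len(used)]
      smin <- blocks$sum_nmin[perm][seq_len(used)]
      wmax <- rowsum(smax, grp)
      wmin <- rowsum(smin, grp)
      min(hp_from_sums(wmax, wmin), na.rm = TRUE)
    }, numeric(1))
  })
  minima <- sort(minima)
  list(cutoff = minima[rank], minima = minima,
       implied_level = rank / n_shuffles)
}

#' Per-method significance thresholds
#'
#' For the bottommost methods (Hp, Tajima's D, Fay & Wu's H, and the iHS
#' empirical P) the cutoff is the k-th smallest non-missing window value with
#' `k = ceiling(q * m)`; for the topmost method (CLR) it is the k-th largest.
#' Windows attaining the cutoff value are flagged (conservative tie
#' inclusion).
#'
#' @param values numeric vector of window statistics (NAs = missing windows).
#' @param direction `"bottommost"` or `"topmost"`.
#' @param q quantile (default 0.01).
#' @param cutoff optional externally derived cutoff (e.g. the Hp shuffle
#'   threshold) overriding the quantile.
#' @return list with `cutoff`, `direction`, `flagged` (logical, NA-safe) and
#'   `n_flagged`.
#' @export
per_method_threshold <- function(values, direction = c("bottommost", "topmost"),
                                 q = 0.01, cutoff = NULL) {
  direction <- match.arg(direction)
  ok <- !is.na(values)
  m <- sum(ok)
  if (m < 100) warning("fewer than 100 non-missing windows; quantile threshold is coarse")
  if (is.null(cutoff)) {
    k <- max(1L, ceiling(q * m))
    srt <- sort(values[ok])
    cutoff <- if (direction == "bottommost") srt[k] else srt[m - k + 1L]
  }
  flagged <- rep(FALSE, length(values))
  flagged[ok] <- if (direction == "bottommost") values[ok] <= cutoff else values[ok] >= cutoff
  if (m > 0 && all(flagged[ok])) warning("degenerate statistic: all windows flagged")
  list(cutoff = cutoff, direction = direction, flagged = flagged,
       n_flagged = sum(flagged))
}

#' Directions of the five scan methods
#' @return named character vector method -> direction
#' @export
method_directions <- function() {
  c(hp = "bottommost", tajima_d = "bottommost", fay_wu_h = "bottommost",
    ihs = "bottommost", clr = "topmost")
}

#' Call consensus sweeps supported by two or more methods
#'
#' Per method, flagged windows are merged into intervals (windows overlap by
#' construction at half-size steps); the genome is then segmented and maximal
#' intervals covered by at least `min_methods` methods are reported with
#' their supporting-method sets.
#'
#' @param flagged named list: per method, a data.frame of flagged windows
#'   (`chrom`, `start`, `end`).
#' @param min_methods minimum supporting methods (default 2).
#' @return data.frame of sweep regions: `chrom`, `start`, `end`, `support`
#'   (comma-joined method ids), `n_methods`.
#' @export
call_consensus_sweeps <- function(flagged, min_methods = 2) {
  merged <- lapply(flagged, function(df) {
    if (is.null(df) || nrow(df) == 0) return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0)))
    merge_intervals(df[, c("chrom", "start", "end")])
  })
  all_iv <- do.call(rbind, lapply(names(merged), function(m) {
    d <- merged[[m]]
    if (nrow(d) > 0) d$method <- m
    d
  }))
  empty <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      support = character(0), n_methods = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(all_iv) || nrow(all_iv) == 0) return(empty)
  out <- list()
  for (ctg in unique(all_iv$chrom)) {
    iv <- all_iv[all_iv$chrom == ctg, , drop = FALSE]
    brk <- sort(unique(c(iv$start, iv$end)))
    if (length(brk) < 2) next
    seg_s <- head(brk, -1); seg_e <- tail(brk, -1)
    cover <- vapply(seq_along(seg_s), function(k) {
      sum(vapply(names(merged), function(m) {
        d <- merged[[m]]
        any(d$chrom == ctg & d$start < seg_e[k] & d$end > seg_s[k])
      }, logical(1)))
    }, numeric(1))
    keep <- cover >= min_methods
    if (!any(keep)) next
    # merge adjacent kept segments into maximal intervals
    runs <- rle(keep)
    pos_end <- cumsum(runs$lengths)
    pos_start <- pos_end - runs$lengths + 1L
    for (ri in which(runs$values)) {
      s <- seg_s[pos_start[ri]]; e <- seg_e[pos_end[ri]]
      # drop zero-length joins where kept segments are not contiguous
      segs <- pos_start[ri]:pos_end[ri]
      contig_ok <- all(seg_s[segs][-1] == seg_e[segs][-length(segs)]) || length(segs) == 1
      pieces <- if (contig_ok) list(c(s, e)) else {
        # split at gaps between consecutive kept segments
        sp <- list(); cs <- seg_s[segs[1]]; ce <- seg_e[segs[1]]
        for (k in segs[-1]) {
          if (seg_s[k] == ce) ce <- seg_e[k]
          else { sp[[length(sp) + 1]] <- c(cs, ce); cs <- seg_s[k]; ce <- seg_e[k] }
        }
        sp[[length(sp) + 1]] <- c(cs, ce)
        sp
      }
      for (pc in pieces) {
        supp <- names(merged)[vapply(names(merged), function(m) {
          d <- merged[[m]]
          any(d$chrom == ctg & d$start < pc[2] & d$end > pc[1])
        }, logical(1))]
        out[[length(out) + 1]] <- data.frame(chrom = ctg, start = pc[1], end = pc[2],
                                             support = paste(supp, collapse = ","),
                                             n_methods = length(supp),
                                             stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Filter positively selected genes inside consensus sweeps
#'
#' Applies the four-rule gene filter: (1) inside the sweeps, 1-kb window
#' statistics are computed per method (except iHS) and the 2% most extreme
#' windows selected, discarding 1-kb windows with fewer than `min_snps`
#' SNPs; (2) genes whose body plus 2-kb promoter overlap no selected window
#' are dropped; (3) evidence from Tajima's D or Hp alone requires at least
#' `min_weak_windows` selected 1-kb windows (these methods are biased toward
#' low-SNP windows); (4) genes containing any SNP with iHS below
#' `ihs_threshold` inside sweeps are added back.
#'
#' @param sweeps consensus sweeps from [call_consensus_sweeps()].
#' @param index an [annotation_index()] with the gene models.
#' @param kb_stats named list of 1-kb window statistic data.frames for
#'   methods `hp`, `tajima_d`, `fay_wu_h`, `clr`: columns `chrom`, `start`,
#'   `end`, `snp_count`, `value`.
#' @param ihs_records per-SNP scores from [ihs_scores()].
#' @param q 1-kb selection quantile (default 0.02).
#' @param min_snps minimum SNPs per 1-kb window (default 2).
#' @param min_weak_windows rule-3 window count for D/Hp-only support
#'   (default 10).
#' @param ihs_threshold rule-4 iHS threshold (default -2).
#' @return data.frame of PSG records with the per-rule trace: selected
#'   window counts per method, promoter flag, rescued-by-iHS flag.
#' @export
filter_psgs <- function(sweeps, index, kb_stats, ihs_records, q = 0.02,
                        min_snps = 2, min_weak_windows = 10, ihs_threshold = -2) {
  genes <- index$genes
  missing_ctg <- setdiff(genes$chrom, names(index$contig_lengths))
  if (length(missing_ctg) > 0)
    stop("gene annotation on unknown contig: ", paste(missing_ctg, collapse = ","))
  in_sweep <- function(chrom, pos0) {
    hit <- rep(FALSE, length(pos0))
    for (i in seq_len(nrow(sweeps)))
      hit <- hit | (chrom == sweeps$chrom[i] & pos0 >= sweeps$start[i] & pos0 < sweeps$end[i])
    hit
  }
  # rule 1: select extreme 1-kb windows inside sweeps, pooled across sweeps
  dirs <- method_directions()
  selected <- lapply(names(kb_stats), function(m) {
    st <- kb_stats[[m]]
    mid <- (st$start + st$end) / 2
    ok <- in_sweep(st$chrom, mid) & st$snp_count >= min_snps & !is.na(st$value)
    st <- st[ok, , drop = FALSE]
    if (nrow(st) == 0) return(st)
    th <- suppressWarnings(per_method_threshold(st$value, dirs[[m]], q = q))
    st[th$flagged, , drop = FALSE]
  })
  names(selected) <- names(kb_stats)
  # rule 4 candidates: extreme-iHS SNPs inside sweeps
  adaptive <- ihs_records[!is.na(ihs_records$ihs) & ihs_records$ihs < ihs_threshold, , drop = FALSE]
  adaptive <- adaptive[in_sweep(adaptive$chrom, adaptive$pos - 1), , drop = FALSE]

  sweep_genes <- genes_overlapping(index, sweeps, use_promoter = TRUE)
  rows <- list()
  for (gid in union(sweep_genes, character(0))) {
    g <- genes[genes$gene_id == gid, , drop = FALSE]
    gs <- min(g$start, g$prom_start); ge <- max(g$end, g$prom_end)
    counts <- vapply(names(selected), function(m) {
      d <- selected[[m]]
      if (nrow(d) == 0) return(0L)
      sum(intervals_overlap(d$chrom, d$start, d$end, g$chrom, gs, ge))
    }, integer(1))
    ihs_hits <- adaptive[adaptive$chrom == g$chrom &
                           (adaptive$pos - 1) >= gs & (adaptive$pos - 1) < ge, , drop = FALSE]
    strong <- sum(counts[c("fay_wu_h", "clr")]) > 0
    weak <- any(counts[c("tajima_d", "hp")] >= min_weak_windows)
    rescued <- nrow(ihs_hits) > 0
    if (!(strong || weak || rescued)) next
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = gid, chrom = g$chrom, start = g$start, end = g$end,
      n_hp = counts[["hp"]], n_tajima_d = counts[["tajima_d"]],
      n_fay_wu_h = counts[["fay_wu_h"]], n_clr = counts[["clr"]],
      promoter_considered = TRUE,
      n_ihs_snps = nrow(ihs_hits),
      ihs_positions = paste(ihs_hits$pos, collapse = ","),
      passed_strong = strong, passed_weak = weak, rescued_by_ihs = rescued,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0), n_hp = integer(0),
                      n_tajima_d = integer(0), n_fay_wu_h = integer(0),
                      n_clr = integer(0), promoter_considered = logical(0),
                      n_ihs_snps = integer(0), ihs_positions = character(0),
                      passed_strong = logical(0), passed_weak = logical(0),
                      rescued_by_ihs = logical(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
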