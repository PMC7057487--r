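#' Run the five-method selection scan on one population
#'
#' Convenience pipeline: computes Hp, Tajima's D, Fay & Wu's H, the iHS
#' window statistic with its empirical P, and the CLR scan on a common
#' window tiling; derives per-method significance thresholds (shuffle-based
#' for Hp, empirical quantiles elsewhere); and calls consensus sweeps
#' supported by at least two methods.
#'
#' @param gt a [genotype_table()] containing the scanned population.
#' @param ancestral per-site coding (`"ref"`/`"alt"`/`NA`).
#' @param population population label to scan (default "domestic").
#' @param contig_lengths named vector of contig lengths.
#' @param window_size scan window in bp (default 40000; step is half).
#' @param q per-method quantile (default 0.01).
#' @param hp_threshold `"shuffle"` (default) or `"quantile"`.
#' @param seed seed for the Hp shuffle null (required when
#'   `hp_threshold = "shuffle"`).
#' @param n_shuffles,shuffle_rank Hp shuffle parameters (default 1000, 50).
#' @param clr_args optional list of extra arguments for [clr_scan()].
#' @param min_methods consensus support requirement (default 2).
#' @return list with `windows`, per-method window statistics (`hp`, `sfs`,
#'   `ihs_windows`, `clr_windows`), `ihs_records`, `clr_scan`, `thresholds`,
#'   `flagged` (per-method flagged windows) and `sweeps`.
#' @export
scan_cohort <- function(gt, ancestral, population = "domestic", contig_lengths,
                        window_size = 40000, q = 0.01,
                        hp_threshold = c("shuffle", "quantile"), seed = NULL,
                        n_shuffles = 1000, shuffle_rank = 50,
                        clr_args = list(), min_methods = 2) {
  hp_threshold <- match.arg(hp_threshold)
  windows <- make_windows(contig_lengths, window_size)
  hp <- window_hp(gt, windows, population)
  sfs <- sfs_scan_windows(gt, windows, ancestral, population)
  recs <- ihs_scores(gt, ancestral, population)
  iw <- ihs_window_stat(recs, windows)
  iw <- empirical_p_by_bins(iw)
  B <- background_sfs(gt, ancestral, population)
  cs <- do.call(clr_scan, c(list(gt = gt, ancestral = ancestral,
                                 population = population, B = B), clr_args))
  cw <- clr_windows(cs, windows)

  th <- list()
  if (hp_threshold == "shuffle") {
    if (is.null(seed)) stop("seed required for the Hp shuffle threshold")
    kb <- make_windows(contig_lengths, 1000, 1000)
    blocks <- window_hp(gt, kb, population)
    sh <- hp_shuffle_threshold(blocks, scan_window_blocks = window_size / 1000,
                               n_shuffles = n_shuffles, rank = shuffle_rank,
                               seed = seed)
    th$hp <- suppressWarnings(per_method_threshold(hp$hp, "bottommost", q,
                                                   cutoff = sh$cutoff))
    th$hp$shuffle <- sh
  } else {
    th$hp <- suppressWarnings(per_method_threshold(hp$hp, "bottommost", q))
  }
  th$tajima_d <- suppressWarnings(per_method_threshold(sfs$tajima_d, "bottommost", q))
  th$fay_wu_h <- suppressWarnings(per_method_threshold(sfs$fay_wu_h, "bottommost", q))
  th$ihs <- suppressWarnings(per_method_threshold(iw$empirical_p, "bottommost", q))
  th$clr <- suppressWarnings(per_method_threshold(cw$clr_max, "topmost", q))

  flagged <- list(hp = windows[th$hp$flagged, , drop = FALSE],
                  tajima_d = windows[th$tajima_d$flagged, , drop = FALSE],
                  fay_wu_h = windows[th$fay_wu_h$flagged, , drop = FALSE],
                  ihs = windows[th$ihs$flagged, , drop = FALSE],
                  clr = windows[th$clr$flagged, , drop = FALSE])
  sweeps <- call_consensus_sweeps(flagged, min_methods = min_methods)
  list(windows = windows, hp = hp, sfs = sfs, ihs_records = recs,
       ihs_windows = iw, clr_scan = cs, clr_windows = cw, thresholds = th,
       flagged = flagged, sweeps = sweeps)
}

#' 1-kb window statistics inside sweep territory
#'
#' Computes the per-method 1-kb statistics the PSG filter consumes
#' (all methods except iHS), on a 1-kb non-overlapping tiling.
#'
#' @param gt a [genotype_table()].
#' @param ancestral per-site coding.
#' @param population population label.
#' @param contig_lengths named vector of contig lengths.
#' @param scan an existing [clr_scan()] result to reuse (else recomputed).
#' @return named list of data.frames (`hp`, `tajima_d`, `fay_wu_h`, `clr`)
#'   with columns `chrom`, `start`, `end`, `snp_count`, `value`.
#' @export
sweep_kb_stats <- function(gt, ancestral, population, contig_lengths,
                           scan = NULL) {
  kb <- make_windows(contig_lengths, 1000, 1000)
  hp <- window_hp(gt, kb, population)
  sfs <- sfs_scan_windows(gt, kb, ancestral, population)
  if (is.null(scan)) scan <- clr_scan(gt, ancestral, population)
  cw <- clr_windows(scan, kb)
  list(
    hp = data.frame(kb, snp_count = hp$snp_count, value = hp$hp),
    tajima_d = data.frame(kb, snp_count = sfs$snp_count, value = sfs$tajima_d),
    fay_wu_h = data.frame(kb, snp_count = sfs$snp_count, value = sfs$fay_wu_h),
    clr = data.frame(kb, snp_count = cw$n_snps, value = cw$clr_max)
  )
}
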