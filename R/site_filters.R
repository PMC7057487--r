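#' Default SNP site-filter thresholds
#'
#' A site is kept only if read depth is strictly below `max_depth`, base
#' quality, mapping quality and variant quality are at or above their minima,
#' and at least `min_alt_reads` reads support the alternate allele.
#'
#' @param max_depth depth must be `< max_depth` (default 100).
#' @param min_base_q base quality `>=` (default 20).
#' @param min_map_q mapping quality `>=` (default 10).
#' @param min_qual variant quality `>=` (default 20).
#' @param min_alt_reads alt-supporting reads `>=` (default 3).
#' @return a named list of thresholds.
#' @export
site_filter_config <- function(max_depth = 100, min_base_q = 20, min_map_q = 10,
                               min_qual = 20, min_alt_reads = 3) {
  list(max_depth = max_depth, min_base_q = min_base_q, min_map_q = min_map_q,
       min_qual = min_qual, min_alt_reads = min_alt_reads)
}

#' Apply the post-calling SNP site filters
#'
#' All five rules must hold for a site to be kept. A missing annotation fails
#' its rule (and is logged in the report) rather than crashing. The operation
#' is order-independent and idempotent.
#'
#' @param sites data.frame with columns `qual`, `depth`, `base_q`, `map_q`,
#'   `alt_reads` (extra columns pass through), e.g. from
#'   [read_vcf_site_info()].
#' @param cfg thresholds from [site_filter_config()].
#' @return list with `kept` (the filtered data.frame), `keep` (logical vector)
#'   and `report` (per-rule failure counts, including missing-annotation
#'   counts, plus totals).
#' @export
apply_site_filters <- function(sites, cfg = site_filter_config()) {
  need <- c("qual", "depth", "base_q", "map_q", "alt_reads")
  for (f in setdiff(need, names(sites))) sites[[f]] <- NA_real_
  pass <- cbind(
    depth     = !is.na(sites$depth)     & sites$depth < cfg$max_depth,
    base_q    = !is.na(sites$base_q)    & sites$base_q >= cfg$min_base_q,
    map_q     = !is.na(sites$map_q)     & sites$map_q >= cfg$min_map_q,
    qual      = !is.na(sites$qual)      & sites$qual >= cfg$min_qual,
    alt_reads = !is.na(sites$alt_reads) & sites$alt_reads >= cfg$min_alt_reads
  )
  keep <- rowSums(pass) == ncol(pass)
  report <- list(
    n_input = nrow(sites),
    n_kept = sum(keep),
    failed = colSums(!pass),
    missing = c(depth = sum(is.na(sites$depth)), base_q = sum(is.na(sites$base_q)),
                map_q = sum(is.na(sites$map_q)), qual = sum(is.na(sites$qual)),
                alt_reads = sum(is.na(sites$alt_reads)))
  )
  list(kept = sites[keep, , drop = FALSE], keep = keep, report = report)
}
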