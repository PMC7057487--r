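#' Build a sliding-window tiling of contigs
#'
#' Windows use 0-based half-open coordinates internally. The default scan
#' geometry is a 40-kb window stepped by half the window size; a 1-kb
#' non-overlapping tiling (`size = step = 1000`) is used for the fine-scale
#' gene filter.
#'
#' @param contig_lengths named numeric vector of contig lengths in bp.
#' @param size window size in bp (default 40000).
#' @param step step in bp; defaults to `size / 2`.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
make_windows <- function(contig_lengths, size = 40000, step = size / 2) {
  if (size <= 0 || step <= 0) stop("size and step must be positive")
  if (step > size) stop("step must not exceed window size")
  if (is.null(names(contig_lengths)))
    names(contig_lengths) <- as.character(seq_along(contig_lengths))
  out <- lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    starts <- integer(0)
    s <- 0
    repeat {
      starts <- c(starts, s)
      if (s + size >= len) break
      s <- s + step
    }
    data.frame(chrom = ctg, start = starts,
               end = pmin(starts + size, len), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# merge overlapping/adjacent intervals (0-based half-open); adjacency means
# sharing >= 1 bp, i.e. strict overlap
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  out <- list()
  for (ctg in unique(df$chrom)) {
    d <- df[df$chrom == ctg, , drop = FALSE]
    cs <- d$start[1]; ce <- d$end[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] < ce) ce <- max(ce, d$end[i])
      else { out[[length(out) + 1L]] <- data.frame(chrom = ctg, start = cs, end = ce); cs <- d$start[i]; ce <- d$end[i] }
    }
    out[[length(out) + 1L]] <- data.frame(chrom = ctg, start = cs, end = ce)
  }
  do.call(rbind, out)
}

# TRUE where interval [s1,e1) overlaps [s2,e2) on the same chrom (vectorised
# over the first set against a single query interval)
intervals_overlap <- function(chrom, start, end, qchrom, qstart, qend) {
  chrom == qchrom & start < qend & end > qstart
}
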