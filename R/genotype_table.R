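#' Phased genotype table
#'
#' The central container of the package: a matrix of phased haplotypes
#' (two rows per diploid sample) over biallelic SNP sites, with 1-based
#' positions (VCF convention), per-site ref/alt alleles and per-sample
#' population labels. Entries are 0 (ref), 1 (alt) or `NA` (missing).
#'
#' @param haplotypes integer/numeric matrix, `2 * n_samples` rows by
#'   `n_sites` columns, values in \{0, 1, NA\}.
#' @param positions integer vector of 1-based site positions, strictly
#'   increasing within each contig.
#' @param chrom contig id, either length 1 (recycled) or one per site.
#' @param ref,alt character vectors of single-base alleles per site.
#' @param samples data.frame with columns `sample` and `population`,
#'   one row per diploid sample, in haplotype-row order.
#' @param phased logical, whether haplotypes carry phase information.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(haplotypes, positions, chrom = "1", ref = NULL,
                           alt = NULL, samples = NULL, phased = TRUE) {
  haplotypes <- as.matrix(haplotypes)
  m <- ncol(haplotypes)
  if (nrow(haplotypes) %% 2L != 0L) stop("haplotype row count must be even")
  if (length(positions) != m) stop("positions length must equal site count")
  if (length(chrom) == 1L) chrom <- rep(chrom, m)
  if (length(chrom) != m) stop("chrom must be length 1 or one per site")
  for (ctg in unique(chrom)) {
    p <- positions[chrom == ctg]
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing within contig ", ctg)
  }
  if (!all(haplotypes %in% c(0L, 1L, NA))) stop("haplotype entries must be 0, 1 or NA")
  n_samp <- nrow(haplotypes) / 2L
  if (is.null(samples)) {
    samples <- data.frame(sample = paste0("s", seq_len(n_samp)),
                          population = rep("pop1", n_samp),
                          stringsAsFactors = FALSE)
  }
  if (nrow(samples) != n_samp) stop("samples must have one row per diploid sample")
  structure(list(
    haplotypes = haplotypes,
    positions = as.integer(positions),
    chrom = as.character(chrom),
    ref = ref %||% rep("A", m),
    alt = alt %||% rep("G", m),
    samples = samples,
    phased = phased
  ), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$haplotypes), "haplotypes (",
      nrow(x$samples), "samples ) x", ncol(x$haplotypes), "sites\n")
  cat("populations:", paste(sprintf("%s=%d", names(table(x$samples$population)),
                                    table(x$samples$population)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of sites in a genotype table
#' @param gt a `genotype_table`
#' @return integer site count
#' @export
n_sites <- function(gt) ncol(gt$haplotypes)

#' Haplotype row indices belonging to a population
#' @param gt a `genotype_table`
#' @param population population label, or `NULL` for all rows
#' @return integer vector of haplotype row indices
#' @export
pop_rows <- function(gt, population = NULL) {
  if (is.null(population)) return(seq_len(nrow(gt$haplotypes)))
  keep <- which(gt$samples$population %in% population)
  if (length(keep) == 0L) stop("no samples in population: ", paste(population, collapse = ","))
  sort(c(2L * keep - 1L, 2L * keep))
}

#' Restrict a genotype table to one population
#' @inheritParams pop_rows
#' @return a `genotype_table` containing only that population's samples
#' @export
gt_subset_pop <- function(gt, population) {
  keep <- which(gt$samples$population %in% population)
  if (length(keep) == 0L) stop("no samples in population: ", paste(population, collapse = ","))
  rows <- sort(c(2L * keep - 1L, 2L * keep))
  genotype_table(gt$haplotypes[rows, , drop = FALSE], gt$positions, gt$chrom,
                 gt$ref, gt$alt, gt$samples[keep, , drop = FALSE], gt$phased)
}

#' Subset a genotype table by site index
#' @param gt a `genotype_table`
#' @param idx integer vector of site (column) indices to retain
#' @return a `genotype_table`
#' @export
gt_subset_sites <- function(gt, idx) {
  genotype_table(gt$haplotypes[, idx, drop = FALSE], gt$positions[idx],
                 gt$chrom[idx], gt$ref[idx], gt$alt[idx], gt$samples, gt$phased)
}

#' Per-site alternate-allele counts and sample sizes
#'
#' @param gt a `genotype_table`
#' @param population optional population label
#' @return data.frame with `n_alt` (alt allele count among non-missing
#'   chromosomes) and `n_chr` (non-missing chromosome count) per site
#' @export
site_allele_counts <- function(gt, population = NULL) {
  rows <- pop_rows(gt, population)
  h <- gt$haplotypes[rows, , drop = FALSE]
  n_alt <- colSums(h, na.rm = TRUE)
  n_chr <- colSums(!is.na(h))
  data.frame(n_alt = n_alt, n_chr = n_chr)
}

# TRUE for sites with a position whose 0-based coordinate falls in [start, end)
sites_in_window <- function(gt, chrom, start, end) {
  gt$chrom == chrom & (gt$positions - 1L) >= start & (gt$positions - 1L) < end
}
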