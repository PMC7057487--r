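#' Read a VCF into a genotype table
#'
#' Only biallelic SNP records are retained (multiallelic and indel records are
#' dropped with a logged count). Phase is preserved; missing calls become `NA`.
#'
#' @param path path to a VCF 4.x file with GT.
#' @param population_map data.frame with columns `sample`, `population`
#'   covering every sample in the file, or `NULL` to place all samples in
#'   population "pop1". Samples in the map that are absent from the VCF are
#'   an error.
#' @return a [genotype_table()]; attribute `"dropped"` carries counts of
#'   dropped multiallelic/indel records.
#' @export
read_vcf <- function(path, population_map = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(fixm)  # single-record files drop dims
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  fix$POS <- as.integer(fix$POS)
  snp <- !is.na(fix$ALT) & !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  dropped <- c(non_biallelic_or_indel = sum(!snp))
  # enforce sorted input before subsetting so the offending record is named
  for (ctg in unique(fix$CHROM)) {
    p <- fix$POS[fix$CHROM == ctg]
    if (any(diff(p) <= 0)) {
      bad <- which(diff(p) <= 0)[1] + 1L
      stop("VCF not sorted: record ", ctg, ":", p[bad], " out of order")
    }
  }
  gtm <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gtm))) gtm <- t(gtm)
  gtm <- gtm[snp, , drop = FALSE]
  samples <- colnames(gtm)
  if (is.null(population_map)) {
    population_map <- data.frame(sample = samples, population = "pop1",
                                 stringsAsFactors = FALSE)
  }
  unknown <- setdiff(population_map$sample, samples)
  if (length(unknown) > 0)
    stop("unknown sample in population_map: ", paste(unknown, collapse = ","))
  missing_map <- setdiff(samples, population_map$sample)
  if (length(missing_map) > 0)
    stop("samples missing from population_map: ", paste(missing_map, collapse = ","))
  pops <- population_map$population[match(samples, population_map$sample)]

  phased <- all(grepl("|", gtm, fixed = TRUE) | is.na(gtm) | gtm == ".")
  m <- sum(snp)
  hap <- matrix(NA_integer_, nrow = 2L * length(samples), ncol = m)
  for (j in seq_along(samples)) {
    g <- gtm[, j]
    g[g == "."] <- NA
    parts <- strsplit(g, "[|/]")
    a1 <- suppressWarnings(as.integer(vapply(parts, function(x) x[1] %||% NA_character_, "")))
    a2 <- suppressWarnings(as.integer(vapply(parts, function(x) if (length(x) > 1) x[2] else NA_character_, "")))
    hap[2L * j - 1L, ] <- a1
    hap[2L * j, ] <- a2
  }
  out <- genotype_table(hap, fix$POS[snp], fix$CHROM[snp], fix$REF[snp],
                        fix$ALT[snp],
                        data.frame(sample = samples, population = pops,
                                   stringsAsFactors = FALSE),
                        phased = phased)
  attr(out, "dropped") <- dropped
  out
}

#' Extract per-site filter annotations from a VCF
#'
#' Pulls QUAL plus the INFO keys `DP` (read depth), `BQ` (base quality),
#' `MQ` (mapping quality) and `AD` (alternate-allele supporting reads) into
#' the site table consumed by [apply_site_filters()]. Absent keys yield `NA`
#' and fail the corresponding rule there.
#'
#' @param path path to a VCF file.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `qual`, `depth`,
#'   `base_q`, `map_q`, `alt_reads`.
#' @export
read_vcf_site_info <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(fixm)
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  num_info <- function(key) suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
             alt = fix$ALT, qual = suppressWarnings(as.numeric(fix$QUAL)),
             depth = num_info("DP"), base_q = num_info("BQ"),
             map_q = num_info("MQ"), alt_reads = num_info("AD"),
             stringsAsFactors = FALSE)
}

#' Write a genotype table as a phased VCF
#'
#' Emits a minimal VCF 4.2 with GT only (and optional INFO columns), the
#' inverse of [read_vcf()] for package-generated data.
#'
#' @param gt a [genotype_table()].
#' @param path output path.
#' @param info optional character vector of INFO strings, one per site.
#' @param contig_lengths optional named vector for `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_vcf_gt <- function(gt, path, info = NULL, contig_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=domestiscan",
               '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth">',
               '##INFO=<ID=BQ,Number=1,Type=Float,Description="RMS base quality">',
               '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
               '##INFO=<ID=AD,Number=1,Type=Integer,Description="Alt-supporting reads">',
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'), con)
  if (!is.null(contig_lengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                       as.integer(contig_lengths)), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gt$samples$sample), collapse = "\t"), con)
  sep <- if (isTRUE(gt$phased)) "|" else "/"
  h <- gt$haplotypes
  n_samp <- nrow(gt$samples)
  gt_str <- matrix("", nrow = n_samp, ncol = ncol(h))
  for (j in seq_len(n_samp)) {
    a1 <- h[2L * j - 1L, ]; a2 <- h[2L * j, ]
    s <- paste(ifelse(is.na(a1), ".", a1), ifelse(is.na(a2), ".", a2), sep = sep)
    gt_str[j, ] <- s
  }
  lines <- paste(gt$chrom, gt$positions, ".", gt$ref, gt$alt, ".", "PASS",
                 info %||% ".", "GT",
                 apply(gt_str, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
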