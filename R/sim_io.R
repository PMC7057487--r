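#' Write a simulated dataset to disk
#'
#' Emits the standard-format files every pipeline stage consumes: a phased
#' VCF, the outgroup FASTA, GFF3 gene models, TSVs for the population map,
#' network edges, set membership and site scores, and a JSON truth manifest.
#' Output is deterministic for a given simulation (no timestamps). On any
#' failure, partially written files are removed before the error is
#' re-thrown.
#'
#' @param sim a `sim_cohort` from [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @param resources optional list from [generate_resources()].
#' @return invisible character vector of the files written.
#' @export
write_dataset <- function(sim, out_dir, resources = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop("partial dataset write cleaned up: ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    f <- file.path(out_dir, "genotypes.vcf")
    write_vcf_gt(sim$gt, f, contig_lengths = c("1" = sim$config$L))
    written <- c(written, f)

    f <- file.path(out_dir, "outgroup.fa")
    seqinr::write.fasta(list(sim$outgroup_seq), names = "outgroup_1", file.out = f)
    written <- c(written, f)

    f <- file.path(out_dir, "popmap.tsv")
    write.table(sim$gt$samples, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, f)

    if (!is.null(resources)) {
      f <- file.path(out_dir, "genes.gff3")
      write_gff3(resources$genes, resources$features, f)
      written <- c(written, f)
      f <- file.path(out_dir, "network.tsv")
      write.table(resources$network, f, sep = "\t", quote = FALSE, row.names = FALSE)
      written <- c(written, f)
      f <- file.path(out_dir, "sets.tsv")
      write.table(resources$membership, f, sep = "\t", quote = FALSE, row.names = FALSE)
      written <- c(written, f)
      if (!is.null(resources$scores)) {
        f <- file.path(out_dir, "scores.tsv")
        write.table(resources$scores, f, sep = "\t", quote = FALSE, row.names = FALSE)
        written <- c(written, f)
      }
    }

    f <- file.path(out_dir, "truth.json")
    truth <- sim$truth
    if (!is.null(resources)) truth$resources <- resources$truth
    jsonlite::write_json(truth, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, f)
    invisible(written)
  }, error = on_fail)
}

# minimal GFF3 writer for gene/exon/UTR models (derived feature types are
# re-computed on load)
write_gff3 <- function(genes, features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(sprintf("%s\tdomestiscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$start + 1L, g$end, g$strand, g$gene_id), con)
    fe <- features[features$gene_id == g$gene_id &
                     features$type %in% c("exon", "UTR5", "UTR3"), , drop = FALSE]
    fe <- fe[order(fe$start), , drop = FALSE]
    for (k in seq_len(nrow(fe))) {
      ty <- switch(fe$type[k], exon = "exon", UTR5 = "five_prime_UTR",
                   UTR3 = "three_prime_UTR")
      writeLines(sprintf("%s\tdomestiscan\t%s\t%d\t%d\t.\t%s\t.\tParent=%s",
                         fe$chrom[k], ty, fe$start[k] + 1L, fe$end[k], g$strand,
                         g$gene_id), con)
    }
  }
  invisible(path)
}

#' Read a written dataset back
#'
#' @param dir directory written by [write_dataset()].
#' @param L genome length (read from the VCF contig header when absent).
#' @return list with `gt`, `outgroup_seq`, `truth`, and (when present)
#'   `index`, `network`, `membership`, `scores`.
#' @export
read_dataset <- function(dir, L = NULL) {
  popmap <- read.table(file.path(dir, "popmap.tsv"), header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
  gt <- read_vcf(file.path(dir, "genotypes.vcf"), popmap)
  og <- seqinr::read.fasta(file.path(dir, "outgroup.fa"), as.string = FALSE,
                           forceDNAtolower = FALSE)
  outgroup_seq <- toupper(as.character(og[[1]]))
  if (is.null(L)) {
    hdr <- readLines(file.path(dir, "genotypes.vcf"), n = 50)
    ctg <- grep("^##contig", hdr, value = TRUE)
    if (length(ctg) > 0) L <- as.integer(sub(".*length=([0-9]+).*", "\\1", ctg[1]))
  }
  out <- list(gt = gt, outgroup_seq = outgroup_seq,
              truth = jsonlite::fromJSON(file.path(dir, "truth.json")))
  gff <- file.path(dir, "genes.gff3")
  if (file.exists(gff) && !is.null(L))
    out$index <- load_annotations(gff, c("1" = L))
  for (nm in c("network", "sets", "scores")) {
    f <- file.path(dir, paste0(ifelse(nm == "sets", "sets", nm), ".tsv"))
    if (file.exists(f))
      out[[if (nm == "sets") "membership" else nm]] <-
        read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  out
}
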