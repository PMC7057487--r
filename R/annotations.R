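#' Build an annotation interval index
#'
#' Combines gene models and per-gene feature intervals into merged,
#' per-category interval sets used for position classification, plus
#' strand-aware 2-kb promoters per gene. Coordinates are 0-based half-open.
#'
#' Classification precedence (highest first):
#' exon > splicing > UTR5 > UTR3 > intron > upstream > downstream > intergenic.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `strand` ("+"/"-"),
#'   `start`, `end` (0-based half-open gene body).
#' @param features data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `type` in exon/splicing/UTR5/UTR3/intron/upstream/downstream.
#' @param contig_lengths named vector of contig lengths.
#' @param promoter_bp promoter length upstream of the strand-aware gene
#'   start (default 2000, clipped at contig edges).
#' @return an object of class `annotation_index`.
#' @export
annotation_index <- function(genes, features, contig_lengths, promoter_bp = 2000) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes)))
  for (i in seq_len(nrow(features))) {
    len <- contig_lengths[[features$chrom[i]]]
    if (is.null(len) || features$end[i] > len || features$start[i] < 0)
      stop("feature outside contig: ", features$gene_id[i], " ",
           features$start[i], "-", features$end[i])
  }
  plus <- genes$strand == "+"
  prom_start <- ifelse(plus, pmax(0, genes$start - promoter_bp), genes$end)
  prom_end <- ifelse(plus, genes$start,
                     pmin(genes$end + promoter_bp,
                          as.numeric(contig_lengths[genes$chrom])))
  genes$prom_start <- prom_start
  genes$prom_end <- prom_end
  cats <- c("exon", "splicing", "UTR5", "UTR3", "intron", "upstream", "downstream")
  merged <- lapply(cats, function(ct) {
    f <- features[features$type == ct, c("chrom", "start", "end"), drop = FALSE]
    merge_intervals(f)
  })
  names(merged) <- cats
  structure(list(genes = genes, features = features, merged = merged,
                 contig_lengths = contig_lengths, promoter_bp = promoter_bp),
            class = "annotation_index")
}

#' Load gene annotations from GFF3 or BED
#'
#' GFF3 `gene` records define gene bodies; `exon`, `five_prime_UTR` and
#' `three_prime_UTR` children define features. Introns are the gaps between
#' exons, with a 2-bp splice-site interval carved from each intron end;
#' exonic UTR sequence is assigned to the UTR categories. Upstream and
#' downstream categories are 1-kb strand-aware flanks of the transcription
#' start/end. Six-column BED input defines gene bodies treated as
#' single-exon models.
#'
#' @param path path to a `.gff3`/`.gff` or `.bed` file.
#' @param contig_lengths named vector of contig lengths.
#' @param flank_bp upstream/downstream category width (default 1000).
#' @param splice_bp splice-site width at each intron end (default 2).
#' @param promoter_bp promoter width (default 2000).
#' @return an [annotation_index()].
#' @export
load_annotations <- function(path, contig_lengths, flank_bp = 1000,
                             splice_bp = 2, promoter_bp = 2000) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    genes <- data.frame(gene_id = bed[[4]], chrom = as.character(bed[[1]]),
                        strand = if (ncol(bed) >= 6) bed[[6]] else "+",
                        start = bed[[2]], end = bed[[3]],
                        stringsAsFactors = FALSE)
    exons <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                        start = genes$start, end = genes$end, type = "exon",
                        stringsAsFactors = FALSE)
    utr5 <- utr3 <- exons[0, ]
  } else {
    gff <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                             quote = "", stringsAsFactors = FALSE)
    names(gff) <- c("chrom", "source", "type", "start", "end", "score",
                    "strand", "phase", "attr")
    attr_val <- function(a, key) {
      m <- regmatches(a, regexpr(paste0(key, "=[^;]+"), a))
      ifelse(lengths(regmatches(a, gregexpr(paste0(key, "=[^;]+"), a))) > 0,
             sub(paste0(key, "="), "", m), NA_character_)
    }
    gff$start <- gff$start - 1L  # to 0-based half-open
    g <- gff[gff$type == "gene", ]
    genes <- data.frame(gene_id = attr_val(g$attr, "ID"), chrom = as.character(g$chrom),
                        strand = g$strand, start = g$start, end = g$end,
                        stringsAsFactors = FALSE)
    sub_feat <- function(ty) {
      s <- gff[gff$type == ty, ]
      if (nrow(s) == 0) return(data.frame(gene_id = character(0), chrom = character(0),
                                          start = numeric(0), end = numeric(0),
                                          type = character(0), stringsAsFactors = FALSE))
      data.frame(gene_id = attr_val(s$attr, "Parent"), chrom = as.character(s$chrom),
                 start = s$start, end = s$end,
                 type = switch(ty, exon = "exon", five_prime_UTR = "UTR5",
                               three_prime_UTR = "UTR3"),
                 stringsAsFactors = FALSE)
    }
    exons <- sub_feat("exon"); utr5 <- sub_feat("five_prime_UTR"); utr3 <- sub_feat("three_prime_UTR")
  }
  features <- derive_features(genes, exons, utr5, utr3, contig_lengths,
                              flank_bp = flank_bp, splice_bp = splice_bp)
  annotation_index(genes, features, contig_lengths, promoter_bp = promoter_bp)
}

# build the disjoint per-gene feature set: exon (minus UTRs), UTR5/UTR3,
# splicing (2 bp at intron ends), intron remainder, strand-aware 1-kb flanks
derive_features <- function(genes, exons, utr5, utr3, contig_lengths,
                            flank_bp = 1000, splice_bp = 2) {
  out <- list()
  add <- function(gene_id, chrom, start, end, type) {
    keep <- end > start
    if (any(keep))
      out[[length(out) + 1L]] <<- data.frame(gene_id = gene_id[keep], chrom = chrom[keep],
                                             start = start[keep], end = end[keep],
                                             type = type, stringsAsFactors = FALSE)
  }
  subtract <- function(s, e, cuts) {
    # subtract a set of intervals (data.frame start/end) from [s, e)
    if (nrow(cuts) == 0) return(data.frame(start = s, end = e))
    cuts <- cuts[order(cuts$start), , drop = FALSE]
    res <- list(); cur <- s
    for (i in seq_len(nrow(cuts))) {
      if (cuts$start[i] > cur) res[[length(res) + 1L]] <- c(cur, min(cuts$start[i], e))
      cur <- max(cur, cuts$end[i])
      if (cur >= e) break
    }
    if (cur < e) res[[length(res) + 1L]] <- c(cur, e)
    if (length(res) == 0) return(data.frame(start = numeric(0), end = numeric(0)))
    m <- do.call(rbind, res)
    data.frame(start = m[, 1], end = m[, 2])
  }
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]; ctg <- genes$chrom[i]
    len <- as.numeric(contig_lengths[[ctg]])
    ex <- exons[exons$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    u5 <- utr5[utr5$gene_id == gid, , drop = FALSE]
    u3 <- utr3[utr3$gene_id == gid, , drop = FALSE]
    add(gid, ctg, u5$start, u5$end, "UTR5")
    add(gid, ctg, u3$start, u3$end, "UTR3")
    # exon minus UTR sequence
    for (k in seq_len(nrow(ex))) {
      cuts <- rbind(u5[, c("start", "end")], u3[, c("start", "end")])
      seg <- subtract(ex$start[k], ex$end[k], cuts)
      add(rep(gid, nrow(seg)), rep(ctg, nrow(seg)), seg$start, seg$end, "exon")
    }
    # introns between consecutive exons, splice sites carved out
    if (nrow(ex) > 1) {
      for (k in seq_len(nrow(ex) - 1)) {
        is_ <- ex$end[k]; ie <- ex$start[k + 1]
        if (ie <= is_) next
        sb <- min(splice_bp, floor((ie - is_) / 2))
        add(gid, ctg, is_, is_ + sb, "splicing")
        add(gid, ctg, ie - sb, ie, "splicing")
        add(gid, ctg, is_ + sb, ie - sb, "intron")
      }
    }
    # strand-aware transcription start/end flanks
    if (genes$strand[i] == "+") {
      add(gid, ctg, max(0, genes$start[i] - flank_bp), genes$start[i], "upstream")
      add(gid, ctg, genes$end[i], min(len, genes$end[i] + flank_bp), "downstream")
    } else {
      add(gid, ctg, genes$end[i], min(len, genes$end[i] + flank_bp), "upstream")
      add(gid, ctg, max(0, genes$start[i] - flank_bp), genes$start[i], "downstream")
    }
  }
  if (length(out) == 0)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0), type = character(0)))
  do.call(rbind, out)
}

#' Classify genomic positions into region categories
#'
#' Assigns every position exactly one of the eight categories by the fixed
#' precedence exon > splicing > UTR5 > UTR3 > intron > upstream > downstream >
#' intergenic.
#'
#' @param index an [annotation_index()].
#' @param chrom contig id (length 1 or per position).
#' @param pos 1-based positions.
#' @return character vector of categories.
#' @export
classify_positions <- function(index, chrom, pos) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  pos0 <- pos - 1
  out <- rep("intergenic", length(pos))
  unset <- rep(TRUE, length(pos))
  for (ct in c("exon", "splicing", "UTR5", "UTR3", "intron", "upstream", "downstream")) {
    iv <- index$merged[[ct]]
    if (nrow(iv) == 0) next
    for (ctg in unique(chrom[unset])) {
      ivc <- iv[iv$chrom == ctg, , drop = FALSE]
      if (nrow(ivc) == 0) next
      sel <- which(unset & chrom == ctg)
      k <- findInterval(pos0[sel], ivc$start)
      hit <- k > 0 & pos0[sel] < ivc$end[pmax(k, 1L)]
      out[sel[hit]] <- ct
      unset[sel[hit]] <- FALSE
    }
  }
  out
}

#' Fraction of territory occupied by each region category
#'
#' @param index an [annotation_index()].
#' @param territory data.frame of intervals (`chrom`, `start`, `end`,
#'   0-based half-open); defaults to the whole genome.
#' @return named numeric vector over the eight categories, summing to 1.
#' @export
region_fractions <- function(index, territory = NULL) {
  if (is.null(territory)) {
    territory <- data.frame(chrom = names(index$contig_lengths), start = 0,
                            end = as.numeric(index$contig_lengths))
  }
  territory <- merge_intervals(territory)
  cats <- c("exon", "splicing", "UTR5", "UTR3", "intron", "upstream",
            "downstream", "intergenic")
  tot <- setNames(numeric(length(cats)), cats)
  for (i in seq_len(nrow(territory))) {
    pos <- seq.int(territory$start[i] + 1L, territory$end[i])
    cl <- classify_positions(index, territory$chrom[i], pos)
    tb <- table(cl)
    tot[names(tb)] <- tot[names(tb)] + as.numeric(tb)
  }
  tot / sum(tot)
}

#' Genes whose body or promoter overlaps a set of intervals
#'
#' @param index an [annotation_index()].
#' @param intervals data.frame (`chrom`, `start`, `end`).
#' @param use_promoter include the 2-kb promoter in the overlap test.
#' @return character vector of gene ids.
#' @export
genes_overlapping <- function(index, intervals, use_promoter = TRUE) {
  g <- index$genes
  body_s <- if (use_promoter) pmin(g$start, g$prom_start) else g$start
  body_e <- if (use_promoter) pmax(g$end, g$prom_end) else g$end
  hit <- rep(FALSE, nrow(g))
  for (i in seq_len(nrow(intervals))) {
    hit <- hit | intervals_overlap(g$chrom, body_s, body_e, intervals$chrom[i],
                                   intervals$start[i], intervals$end[i])
  }
  g$gene_id[hit]
}
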