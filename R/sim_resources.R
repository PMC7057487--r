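#' Generate annotation, network, gene-set and site-score resources
#'
#' Builds the side inputs every downstream analysis needs, with known
#' ground truth: non-overlapping gene models with UTR/exon/intron structure,
#' a scale-free interaction network by preferential attachment, random gene
#' sets (optionally with a planted enriched set), and per-site
#' rejected-substitution scores (optionally with deleterious status planted
#' on sites whose derived allele rose in frequency in the domestic cohort).
#'
#' @param L genome length in bp.
#' @param n_genes number of gene models (default 40).
#' @param n_sets number of gene sets (default 20).
#' @param pa_power preferential-attachment power for the network (default 1).
#' @param seed RNG seed (required).
#' @param gt optional [genotype_table()]: enables site scores.
#' @param ancestral per-site coding for `gt` (needed with `deleterious`
#'   mode "shifted").
#' @param deleterious list `n` (scored deleterious sites), `mode`
#'   (`"random"` or `"shifted"`), `shift` (minimum domestic-minus-wild
#'   derived frequency difference for mode "shifted").
#' @param planted_set optional list `set_id`, `genes` forcing one set's
#'   membership (for end-to-end enrichment recovery tests).
#' @return list with `genes`, `features`, `index` (an
#'   [annotation_index()]), `network` (edge data.frame), `membership`,
#'   `scores` (or `NULL`), and `truth`.
#' @export
generate_resources <- function(L, n_genes = 40, n_sets = 20, pa_power = 1,
                               seed, gt = NULL, ancestral = NULL,
                               deleterious = list(n = 100, mode = "random", shift = 0.2),
                               planted_set = NULL) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (n_genes < 1) stop("n_genes must be >= 1")
  with_seed(seed, {
    gene_ids <- sprintf("gene%03d", seq_len(n_genes))
    genes <- exons <- utr5 <- utr3 <- list()
    cursor <- 4000
    for (gi in seq_len(n_genes)) {
      n_ex <- sample(2:5, 1)
      ex_len <- sample(150:400, n_ex, replace = TRUE)
      in_len <- sample(400:1500, max(0, n_ex - 1), replace = TRUE)
      u5 <- sample(100:200, 1); u3 <- sample(150:400, 1)
      body <- u5 + sum(ex_len) + sum(in_len) + u3
      gs <- cursor
      ge <- gs + body
      if (ge + 4000 > L) stop("genes cannot fit in L (placed ", gi - 1, " of ", n_genes, ")")
      strand <- sample(c("+", "-"), 1)
      genes[[gi]] <- data.frame(gene_id = gene_ids[gi], chrom = "1",
                                strand = strand, start = gs, end = ge,
                                stringsAsFactors = FALSE)
      # genomic layout left to right: [five-prime UTR][exons/introns][three-prime UTR]
      # (swap UTR labels on the minus strand)
      left_utr <- c(gs, gs + u5); right_utr <- c(ge - u3, ge)
      if (strand == "+") {
        utr5[[length(utr5) + 1]] <- data.frame(gene_id = gene_ids[gi], chrom = "1",
                                               start = left_utr[1], end = left_utr[2])
        utr3[[length(utr3) + 1]] <- data.frame(gene_id = gene_ids[gi], chrom = "1",
                                               start = right_utr[1], end = right_utr[2])
      } else {
        utr3[[length(utr3) + 1]] <- data.frame(gene_id = gene_ids[gi], chrom = "1",
                                               start = left_utr[1], end = left_utr[2])
        utr5[[length(utr5) + 1]] <- data.frame(gene_id = gene_ids[gi], chrom = "1",
                                               start = right_utr[1], end = right_utr[2])
      }
      p <- gs + u5
      for (k in seq_len(n_ex)) {
        exons[[length(exons) + 1]] <- data.frame(gene_id = gene_ids[gi], chrom = "1",
                                                 start = p, end = p + ex_len[k])
        p <- p + ex_len[k] + if (k < n_ex) in_len[k] else 0
      }
      cursor <- ge + sample(4000:9000, 1)
    }
    genes <- do.call(rbind, genes)
    exons <- do.call(rbind, exons)
    utr5 <- do.call(rbind, utr5)
    utr3 <- do.call(rbind, utr3)
    # UTRs are modelled inside the outermost exons for the exon-minus-UTR carve
    exons2 <- exons
    contig_lengths <- c("1" = L)
    features <- derive_features(genes, exons2, utr5, utr3, contig_lengths)
    index <- annotation_index(genes, features, contig_lengths)

    net <- igraph::sample_pa(n_genes, power = pa_power, m = min(2, n_genes - 1),
                             directed = FALSE)
    igraph::V(net)$name <- gene_ids
    network <- igraph::as_data_frame(net, what = "edges")
    names(network) <- c("gene_a", "gene_b")

    membership <- do.call(rbind, lapply(seq_len(n_sets), function(si) {
      sz <- sample(5:min(25, n_genes), 1)
      data.frame(set_id = sprintf("set%02d", si),
                 gene = sample(gene_ids, sz), stringsAsFactors = FALSE)
    }))
    if (!is.null(planted_set)) {
      membership <- membership[membership$set_id != planted_set$set_id, , drop = FALSE]
      membership <- rbind(membership,
                          data.frame(set_id = planted_set$set_id,
                                     gene = planted_set$genes,
                                     stringsAsFactors = FALSE))
    }

    scores <- NULL; del_pos <- integer(0)
    if (!is.null(gt)) {
      m <- n_sites(gt)
      n_del <- min(deleterious$n, m)
      if (identical(deleterious$mode, "shifted")) {
        if (is.null(ancestral)) stop("ancestral coding needed for shifted deleterious sites")
        fw <- site_allele_counts(gt, "wild")
        fd <- site_allele_counts(gt, "domestic")
        der_w <- ifelse(ancestral == "ref", fw$n_alt, fw$n_chr - fw$n_alt) / pmax(1, fw$n_chr)
        der_d <- ifelse(ancestral == "ref", fd$n_alt, fd$n_chr - fd$n_alt) / pmax(1, fd$n_chr)
        diff <- der_d - der_w
        cand <- which(diff >= deleterious$shift)
        del_idx <- if (length(cand) >= n_del) sample(cand, n_del) else
          order(-diff)[seq_len(n_del)]
      } else {
        del_idx <- sample.int(m, n_del)
      }
      rs <- rnorm(m, 0, 1)
      rs[del_idx] <- rnorm(n_del, 3.5, 0.5)
      scores <- data.frame(chrom = gt$chrom, pos = gt$positions, rs = rs,
                           stringsAsFactors = FALSE)
      del_pos <- sort(gt$positions[del_idx])
    }
    list(genes = genes, features = features, index = index, network = network,
         membership = membership, scores = scores,
         truth = list(seed = seed, deleterious_positions = del_pos,
                      planted_set = planted_set))
  })
}
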