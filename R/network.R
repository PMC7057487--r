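#' Hub-degree resampling test
#'
#' Tests whether a gene set sits at unusually connected (hub) positions of
#' an interaction network. The sub-network induced by the target genes plus
#' their direct interactors is extracted and the targets' degree ranks
#' within it computed; the same is done for `n_resamples` random gene sets
#' of equal size, whose per-position median sorted ranks form the reported
#' null rank profile. The test statistic is the rank-sum of the target genes
#' against the rest of their sub-network, normalized by sub-network size so
#' that draws with different closures are comparable (equivalently, the mean
#' normalized degree rank). Its null distribution comes from the resamples
#' themselves: the P value is the add-one fraction of resampled gene sets
#' with an at-least-as-extreme statistic. (An analytic rank-sum null against
#' the median profile is degenerate — the median profile has far less
#' variance than any single draw — so the procedure's own resampling null is
#' used for calibration.)
#'
#' @param network an igraph graph, or a data.frame edge list
#'   (`gene_a`, `gene_b`).
#' @param psg character vector of target genes (must be network nodes).
#' @param n_resamples number of random gene sets (default 1000).
#' @param seed RNG seed (required).
#' @param alternative `"greater"` (default: the targets have higher degree
#'   ranks), `"less"`, or `"two.sided"`.
#' @return list with `p_value`, `statistic` (the observed rank-sum of the
#'   targets against the median profile), `psg_ranks`, `null_ranks` (median
#'   profile), `psg_degrees`.
#' @export
hub_degree_test <- function(network, psg, n_resamples = 1000, seed,
                            alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  g <- if (igraph::is_igraph(network)) network else
    igraph::graph_from_data_frame(network[, 1:2], directed = FALSE)
  g <- igraph::simplify(g)
  nodes <- igraph::V(g)$name
  if (length(psg) > length(nodes)) stop("more target genes than network nodes")
  if (!all(psg %in% nodes)) stop("target genes absent from the network: ",
                                 paste(setdiff(psg, nodes), collapse = ","))
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  k <- length(psg)
  subnet_ranks <- function(set) {
    set_idx <- match(set, nodes)
    nb <- which(Matrix::colSums(A[set_idx, , drop = FALSE]) > 0)
    closure <- union(set_idx, nb)
    deg <- Matrix::rowSums(A[closure, closure, drop = FALSE])
    r <- rank(deg)
    # normalized ranks in (0, 1): comparable across closure sizes
    list(ranks = r[match(set_idx, closure)], m = length(closure))
  }
  stat_of <- function(sr) mean(sr$ranks / (sr$m + 1))
  obs <- subnet_ranks(psg)
  resamples <- with_seed(seed, {
    lapply(seq_len(n_resamples), function(i) subnet_ranks(sample(nodes, k)))
  })
  w_obs <- stat_of(obs)
  w_null <- vapply(resamples, stat_of, numeric(1))
  p_ge <- (1 + sum(w_null >= w_obs)) / (n_resamples + 1)
  p_le <- (1 + sum(w_null <= w_obs)) / (n_resamples + 1)
  p <- switch(alternative, greater = p_ge, less = p_le,
              two.sided = min(1, 2 * min(p_ge, p_le)))
  null_profile <- apply(vapply(resamples, function(s) sort(s$ranks), numeric(k)),
                        1, median)
  deg_full <- Matrix::rowSums(A)[match(psg, nodes)]
  list(p_value = p, statistic = w_obs, psg_ranks = sort(obs$ranks),
       null_ranks = null_profile, psg_degrees = deg_full)
}

#' Cross-species convergence of positively selected genes
#'
#' Counts how many species recurrently detect each gene (after optional
#' orthology mapping), summarises sharing by multiplicity, and tests
#' families/pathways shared by at least `min_species` species for
#' enrichment among the pooled targets via [set_enrichment()].
#'
#' @param psg_tables named list (one element per species) of gene id
#'   vectors.
#' @param orthology optional data.frame mapping `gene` to `ortholog`;
#'   unmapped ids are reported and excluded.
#' @param membership optional data.frame (`set_id`, `gene`) of family or
#'   pathway membership in the orthology namespace.
#' @param background background gene universe for enrichment (defaults to
#'   all genes in `membership`).
#' @param min_species sharing filter (default 2).
#' @param correction multiple-testing correction for the enrichment.
#' @return list with `multiplicity` (gene, n_species), `shared_genes`
#'   (multiplicity >= `min_species`), `set_sharing` (set_id, n_species),
#'   `enrichment` (from [set_enrichment()] on sets shared by
#'   >= `min_species` species), and `unmapped`.
#' @export
cross_species_convergence <- function(psg_tables, orthology = NULL,
                                      membership = NULL, background = NULL,
                                      min_species = 2, correction = "BH") {
  unmapped <- character(0)
  mapped <- lapply(psg_tables, function(genes) {
    if (is.null(orthology)) return(unique(genes))
    idx <- match(genes, orthology$gene)
    unmapped <<- c(unmapped, genes[is.na(idx)])
    unique(orthology$ortholog[idx[!is.na(idx)]])
  })
  all_genes <- unique(unlist(mapped))
  mult <- vapply(all_genes, function(g) sum(vapply(mapped, function(s) g %in% s, logical(1))), integer(1))
  multiplicity <- data.frame(gene = all_genes, n_species = mult,
                             stringsAsFactors = FALSE)
  multiplicity <- multiplicity[order(-multiplicity$n_species, multiplicity$gene), ]
  out <- list(multiplicity = multiplicity,
              shared_genes = multiplicity$gene[multiplicity$n_species >= min_species],
              unmapped = unique(unmapped))
  if (!is.null(membership)) {
    set_species <- vapply(unique(membership$set_id), function(s) {
      genes <- membership$gene[membership$set_id == s]
      sum(vapply(mapped, function(sp) any(sp %in% genes), logical(1)))
    }, integer(1))
    out$set_sharing <- data.frame(set_id = unique(membership$set_id),
                                  n_species = set_species, stringsAsFactors = FALSE)
    shared_sets <- out$set_sharing$set_id[out$set_sharing$n_species >= min_species]
    bg <- background %||% unique(membership$gene)
    pooled <- intersect(all_genes, bg)
    if (length(shared_sets) > 0 && length(pooled) > 0) {
      memb <- membership[membership$set_id %in% shared_sets, , drop = FALSE]
      out$enrichment <- set_enrichment(pooled, bg, memb, correction = correction)
    }
  }
  out
}
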