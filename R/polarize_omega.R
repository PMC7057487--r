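#' Polarize alleles against an outgroup
#'
#' Per site: if exactly two alleles are observed across the wild and
#' domestic cohorts and one matches the outgroup base, the outgroup base is
#' the ancestral allele and the other observed allele is derived. Sites with
#' three or more alleles across outgroup + cohorts are skipped
#' (`triallelic-skip`); two observed alleles with a non-matching (or
#' missing) outgroup base give `outgroup-mismatch-skip`.
#'
#' @param outgroup character vector of outgroup bases per site (NA = missing).
#' @param wild,domestic lists (or character vectors) of observed alleles per
#'   site in each cohort.
#' @return data.frame with `ancestral`, `derived`, `status`.
#' @export
polarize_alleles <- function(outgroup, wild, domestic) {
  if (!is.list(wild)) wild <- as.list(wild)
  if (!is.list(domestic)) domestic <- as.list(domestic)
  m <- length(outgroup)
  anc <- der <- rep(NA_character_, m)
  status <- character(m)
  for (i in seq_len(m)) {
    obs <- unique(c(wild[[i]], domestic[[i]]))
    obs <- obs[!is.na(obs) & obs %in% c("A", "C", "G", "T")]
    og <- outgroup[i]
    if (length(obs) >= 3) {
      status[i] <- "triallelic-skip"
    } else if (is.na(og) || !og %in% obs) {
      status[i] <- "outgroup-mismatch-skip"
    } else if (length(obs) == 2) {
      anc[i] <- og
      der[i] <- setdiff(obs, og)
      status[i] <- "ok"
    } else {
      # monomorphic within the cohorts: nothing to polarize
      status[i] <- "outgroup-mismatch-skip"
    }
  }
  data.frame(ancestral = anc, derived = der, status = status,
             stringsAsFactors = FALSE)
}

#' Polarize a genotype table against an outgroup sequence
#'
#' Convenience wrapper around [polarize_alleles()]: the observed alleles at
#' each site are those actually carried by the wild and domestic samples,
#' and the outgroup base is read from a sequence string at each position.
#'
#' @param gt a [genotype_table()].
#' @param outgroup_seq outgroup sequence as a single character string (or
#'   character vector of bases) on the same coordinates.
#' @param wild,domestic population labels.
#' @return list with `ancestral` (`"ref"`/`"alt"`/`NA` per site, the coding
#'   used by the scan modules) and the full `table` from
#'   [polarize_alleles()].
#' @export
polarize_gt <- function(gt, outgroup_seq, wild = "wild", domestic = "domestic") {
  if (length(outgroup_seq) == 1L) outgroup_seq <- strsplit(outgroup_seq, "")[[1]]
  og <- toupper(outgroup_seq[gt$positions])
  obs_alleles <- function(pop) {
    ac <- site_allele_counts(gt, pop)
    lapply(seq_len(n_sites(gt)), function(i) {
      a <- character(0)
      if (ac$n_alt[i] < ac$n_chr[i]) a <- c(a, gt$ref[i])
      if (ac$n_alt[i] > 0) a <- c(a, gt$alt[i])
      a
    })
  }
  tab <- polarize_alleles(og, obs_alleles(wild), obs_alleles(domestic))
  ancestral <- ifelse(tab$status == "ok",
                      ifelse(tab$ancestral == gt$ref, "ref", "alt"), NA_character_)
  list(ancestral = ancestral, table = tab)
}

# standard genetic code, indexed by codon string
codon_aa <- function(codon) {
  seqinr::translate(strsplit(toupper(codon), "")[[1]])
}

#' Nonsynonymous/synonymous site opportunities of a CDS
#'
#' Counting-based (Nei-Gojobori style) mutational opportunities: each codon
#' position contributes the fraction of its three possible substitutions
#' that are synonymous to `Ls`, the remainder to `Ln`. Reference stop codons
#' are skipped.
#'
#' @param cds coding sequence (character string, length divisible by 3).
#' @return list with `Ln`, `Ls`.
#' @export
cds_site_opportunities <- function(cds) {
  s <- strsplit(toupper(cds), "")[[1]]
  if (length(s) %% 3 != 0) stop("CDS length not divisible by 3")
  Ln <- Ls <- 0
  bases <- c("A", "C", "G", "T")
  for (c0 in seq(1, length(s), by = 3)) {
    codon <- s[c0:(c0 + 2)]
    aa0 <- codon_aa(paste(codon, collapse = ""))
    if (aa0 == "*") next
    for (k in 1:3) {
      syn <- 0
      for (b in setdiff(bases, codon[k])) {
        mut <- codon; mut[k] <- b
        if (codon_aa(paste(mut, collapse = "")) == aa0) syn <- syn + 1
      }
      Ls <- Ls + syn / 3
      Ln <- Ln + 1 - syn / 3
    }
  }
  list(Ln = Ln, Ls = Ls)
}

#' Classify a derived substitution as synonymous or nonsynonymous
#'
#' Substitutes the ancestral and derived alleles into the reference codon
#' context and compares the encoded amino acids.
#'
#' @param cds reference coding sequence (character string).
#' @param cds_pos 1-based position within the CDS.
#' @param ancestral,derived single bases.
#' @return `"synonymous"`, `"nonsynonymous"`, or `"stop-codon"` when the
#'   reference codon is a stop.
#' @export
classify_substitution <- function(cds, cds_pos, ancestral, derived) {
  s <- strsplit(toupper(cds), "")[[1]]
  ci <- (cds_pos - 1) %/% 3
  within <- (cds_pos - 1) %% 3 + 1
  codon <- s[(3 * ci + 1):(3 * ci + 3)]
  anc_codon <- codon; anc_codon[within] <- toupper(ancestral)
  der_codon <- codon; der_codon[within] <- toupper(derived)
  aa_a <- codon_aa(paste(anc_codon, collapse = ""))
  aa_d <- codon_aa(paste(der_codon, collapse = ""))
  if (aa_a == "*" ) return("stop-codon")
  if (aa_a == aa_d) "synonymous" else "nonsynonymous"
}

#' Per-individual count-based dN/dS (omega)
#'
#' For every polarized coding SNP, each derived allele copy carried by an
#' individual is classified synonymous or nonsynonymous by substitution into
#' the reference codon; omega is the individual's `(Dn/Ln) / (Ds/Ls)` with
#' site opportunities computed once from the reference CDS. A genic contrast
#' of these per-individual ratios between cohorts preserves the wild-versus-
#' domestic comparison without maximum-likelihood rate estimation.
#'
#' @param gt a [genotype_table()].
#' @param cds_models data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open, single contiguous CDS per gene), `strand` ("+"
#'   only at present).
#' @param ref_seq reference sequence string covering the contig.
#' @param ancestral per-site coding (`"ref"`/`"alt"`/`NA`).
#' @return data.frame per individual: `sample`, `population`, `Dn`, `Ds`,
#'   `Ln`, `Ls`, `omega` (`NA` flagged when `Ds = 0`).
#' @export
omega_per_individual <- function(gt, cds_models, ref_seq, ancestral) {
  if (length(ref_seq) == 1L) ref_seq <- strsplit(ref_seq, "")[[1]]
  Ln <- Ls <- 0
  site_class <- rep(NA_character_, n_sites(gt))
  for (gi in seq_len(nrow(cds_models))) {
    g <- cds_models[gi, ]
    if (g$strand != "+") stop("only plus-strand CDS models are supported")
    cds_len <- g$end - g$start
    if (cds_len %% 3 != 0) {
      warning("CDS length of ", g$gene_id, " not divisible by 3; gene skipped")
      next
    }
    cds <- paste(ref_seq[(g$start + 1):g$end], collapse = "")
    opp <- cds_site_opportunities(cds)
    Ln <- Ln + opp$Ln; Ls <- Ls + opp$Ls
    in_cds <- which(gt$chrom == g$chrom & (gt$positions - 1) >= g$start &
                      (gt$positions - 1) < g$end & !is.na(ancestral))
    for (i in in_cds) {
      anc_base <- if (ancestral[i] == "ref") gt$ref[i] else gt$alt[i]
      der_base <- if (ancestral[i] == "ref") gt$alt[i] else gt$ref[i]
      cds_pos <- gt$positions[i] - g$start
      cl <- classify_substitution(cds, cds_pos, anc_base, der_base)
      if (cl %in% c("synonymous", "nonsynonymous")) site_class[i] <- cl
    }
  }
  der_code <- ifelse(ancestral == "ref", 1L, 0L)  # haplotype value meaning derived
  n_samp <- nrow(gt$samples)
  out <- data.frame(sample = gt$samples$sample, population = gt$samples$population,
                    Dn = 0L, Ds = 0L, Ln = Ln, Ls = Ls, omega = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(n_samp)) {
    h <- gt$haplotypes[c(2L * j - 1L, 2L * j), , drop = FALSE]
    der_copies <- colSums(h == matrix(der_code, 2, n_sites(gt), byrow = TRUE), na.rm = TRUE)
    out$Dn[j] <- sum(der_copies[which(site_class == "nonsynonymous")])
    out$Ds[j] <- sum(der_copies[which(site_class == "synonymous")])
  }
  has_s <- out$Ds > 0 & out$Ls > 0 & out$Ln > 0
  out$omega[has_s] <- (out$Dn[has_s] / out$Ln[has_s]) / (out$Ds[has_s] / out$Ls[has_s])
  out
}
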