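---
title: "Methods: window-based selection scans and convergence analyses for domestication cohorts"
author: "domestiscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window-based selection scans and convergence analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domestiscan)
```

# Scope and model

`domestiscan` contrasts a wild and a domestic cohort of one species to locate
genomic regions shaped by artificial selection, and to characterise the
downstream consequences (gene-level targets, genetic load, enrichment of
adaptive mutations, network position of the selected genes). The pipeline is
organised around five window statistics computed on a sliding tiling
(default 40 kb, stepped by half a window; 100 kb is conventional for species
with longer-range LD):

* **Pooled heterozygosity (Hp).** Per window the major and minor allele
  counts of the contained SNPs are summed and combined as
  $H_p = 2\sum n_{max} \sum n_{min} / (\sum n_{max} + \sum n_{min})^2$;
  selective sweeps drive it toward 0. Its significance threshold is not a
  quantile but a shuffle null: the genome is cut into 1-kb blocks of
  $(\sum n_{max}, \sum n_{min})$, block order is permuted 1000 times to
  destroy LD, scan windows are reassembled from consecutive shuffled blocks,
  and the genome-wide minimum recorded per shuffle; the 50th lowest of the
  1000 minima is the cutoff, an implied significance level of
  $50/1000 = 0.05$.
* **Tajima's D.** $(\hat\theta_\pi - \hat\theta_w) / \sqrt{\widehat{Var}}$
  from the unfolded site frequency spectrum, with
  $\hat\theta_\pi = \sum_i 2 S_i i (n - i) / (n(n-1))$ and
  $\hat\theta_w = S / a_1$. The variance uses the Tajima (1989) constants
  $a_1 \dots e_2$, $Var = e_1 S + e_2 S(S-1)$ — the canonical denominator
  used by VCFtools, which the source statistics were originally computed
  with.
* **Fay & Wu's H.** Numerator $\hat\theta_\pi - \hat\theta_H$ with
  $\hat\theta_H = \sum_i 2 S_i i^2/(n(n-1))$; an excess of high-frequency
  derived alleles — the hallmark of hitchhiking — makes it negative. The
  normalisation follows Zeng et al. (2006): since
  $\theta_\pi - \theta_H = 2(\theta_\pi - \theta_L)$, the statistic is the
  numerator over twice $\sqrt{Var(\hat\theta_\pi - \hat\theta_L)}$, with
  $\theta$ and $\theta^2$ estimated by $S/a_1$ and $S(S-1)/(a_1^2+a_2)$.
* **iHS.** For each core SNP with known ancestral state and minor allele
  frequency above 5%, EHH decay curves are walked in both directions for the
  ancestral and derived alleles, integrated by trapezoid until EHH falls
  below 0.05 (with linear interpolation to the crossing), and the log-ratio
  $\ln(iHH_A/iHH_D)$ standardized to mean 0, SD 1 within derived-frequency
  bins of width 0.05 (bins with fewer than 20 SNPs are left unstandardized).
  The window statistic is the proportion of SNPs with iHS < −2; its
  empirical P is assigned within bins of similar defined-SNP count
  (increment 10, bins with fewer than 20 windows removed) as the fraction of
  windows with a strictly larger statistic.
* **Composite likelihood ratio (CLR).** A SweepFinder-style scan: the
  genome-wide unfolded SFS (with one pseudo-count per class) is the null;
  the alternative models a sweep at the focal position, where a lineage at
  distance $d$ escapes with probability $p_e = 1 - e^{-\alpha d}$,
  $\alpha = r\ln(2N)/s$. Sites with $\alpha d > 12$ are excluded — at the
  cutoff $p_e = 0.999994$ and the model has collapsed back to the
  background. Escaped lineages retain their original alleles (a
  hypergeometric draw from a background configuration sampled from the
  null SFS); non-escaped lineages coalesce onto the swept haplotype, taken
  to carry the ancestral allele; the distribution is renormalized over
  segregating outcomes. At every SNP, CLR
  $= 2(\max_\alpha \sum \ln P_{sweep} - \sum \ln P_{null})$, clipped at 0,
  with $\alpha$ maximized over a fixed 32-point log grid
  ($10^{-7}..10^{-2}$ per bp) for determinism. The window statistic is the
  window maximum.

Per-method thresholds flag the bottommost 1% of windows (topmost for CLR;
lowest-1% empirical P for iHS; the shuffle cutoff for Hp), with ties at the
cutoff included. Regions supported by **at least two methods** after
per-method merging become consensus sweeps. Genes then pass a four-rule
filter: (1) 1-kb statistics inside the sweeps are recomputed per method
(except iHS) and the 2% most extreme 1-kb windows selected, discarding
windows with fewer than 2 SNPs; (2) a gene must be touched by a selected
window within its body or 2-kb promoter; (3) Tajima's D or Hp evidence alone
requires at least 10 selected windows (those statistics are biased toward
low-SNP windows); (4) genes containing any sweep SNP with iHS < −2 are
added back.

## Introgression

`f4_statistic()`/`f4_ztest()` implement the four-population test: the mean
over SNPs of $(p_A - p_B)(p_C - p_D)$ is zero under a strict tree
((A,B),(C,D)); its standard error comes from an unweighted delete-one block
jackknife over consecutive SNP blocks (100,000 SNPs at genome scale,
configurable down for desk-scale data; a trailing remainder shorter than
half a block is merged). $Z = f_4/SE$ is approximately standard normal under
the null; $Z > 4$ indicates gene flow between A and C or between B and D,
$Z < -4$ between A and D or between B and C.

## Downstream procedures

* **Polarization** against an outgroup consensus: a site with exactly two
  alleles across the cohorts, one matching the outgroup base, is polarized;
  three or more cohort alleles are skipped, as are sites whose outgroup
  base matches neither allele.
* **Count-based dN/dS.** Each derived allele in coding sequence is
  classified synonymous/nonsynonymous by substitution into the reference
  codon; per-individual $\omega = (D_n/L_n)/(D_s/L_s)$ with Nei–Gojobori
  style mutational-opportunity site counts from the reference CDS. This is a
  deliberate, documented replacement of maximum-likelihood rate estimation:
  the quantity of interest is the wild-versus-domestic *contrast* of
  per-individual ratios, which counting preserves.
* **Deleterious burden.** Sites with a rejected-substitution score above 2
  are deleterious; the 2×2 table of deleterious/benign derived allele counts
  in wild versus domestic cohorts is tested by chi-square (Fisher fallback
  for empty classes), with per-cohort mean derived frequencies reported.
* **Region enrichment** of putatively adaptive mutations (sweep SNPs with
  iHS < −2) over the eight genomic categories (exon, splicing, UTR5, UTR3,
  intron, 1-kb upstream/downstream, intergenic; precedence in that order):
  expected counts are territory bp fractions times the total, one
  goodness-of-fit chi-square per region, Bonferroni-corrected; regions with
  an expected count below 5 (splicing, UTRs at desk scale) use the exact
  binomial test instead, where the chi-square approximation is
  anti-conservative.
* **Set enrichment** (gene families, pathways, trait tables, cross-species
  shared families): one-sided Fisher test computed as the hypergeometric
  upper tail, BH correction by default, Bonferroni where that is the
  convention for the analysis.
* **Hub-degree test.** The sub-network induced by the target genes plus
  their direct interactors is extracted and the targets' degree ranks
  within it computed; 1000 equally sized random gene sets are processed
  identically, their per-position median sorted ranks forming the reported
  null rank profile. The test statistic is the targets' mean degree rank
  normalized by sub-network size, and its P value is the add-one fraction
  of resampled sets with an at-least-as-extreme statistic. (A textbook
  two-sample rank-sum of target ranks against the *median* profile is both
  mis-calibrated — the median profile has far less variance than any single
  draw — and saturated for true hubs; the resampling null the procedure
  already generates fixes both, and is what makes the null P distribution
  approximately uniform.)

# The synthetic-data generator

Real domestication cohorts (the motivating datasets span chicken, pig and
dog resequencing panels) are not redistributable at package scale, so every
stage is exercised on simulated cohorts with exact ground truth.

`simulate_cohort()` runs a discrete-generation Wright–Fisher forward
simulation of two populations of diploid size $N$ descending from a shared
standing-variation pool: sites are seeded at mutation–drift equilibrium
(expected counts $\theta L / i$ for frequency class $i$) and assigned to
haplotypes at linkage equilibrium, after which both populations evolve with
per-generation mutation, recombination (Poisson crossovers, uniform
breakpoints) and multinomial resampling. The domestic lineage passes a
founding bottleneck and, optionally, a hard sweep: a single beneficial copy
(fitness $1+s$ per allele) arising in the first bottleneck generation,
restarted (up to 100 times) until its frequency is at least 0.95 at
sampling. The outgroup sequence is the ancestral sequence with divergence
substitutions added outside SNP positions, so polarization truth is exact.

Default parameters and why:

| parameter | default | rationale |
|---|---|---|
| `N` | 200 diploids | desk-scale effective size; all times scale with $2N$ |
| `L` | 1 Mb | one desk-scale "genome"; 49 overlapping 40-kb windows |
| `mu` | 4e-7 /bp/gen | inflated so $\theta = 4N\mu = 3.2\times10^{-4}$ yields ~1500 SNPs in a combined sample |
| `r` | 2e-7 /bp/gen | $\rho/\theta = 0.5$, bird-like; sets the hitchhiking footprint (~80 kb) to a few windows |
| `split_gens` | 100 | the sweep completes at or just before sampling, keeping its frequency-spectrum and haplotype signals fresh |
| bottleneck | ×0.1 for 20 gens | domestic/wild diversity ratio ≈ 0.65, matching the magnitude seen in real domestication panels |
| sweep | $s = 0.05$, 1 copy | a hard sweep from a single origin; weaker/softer sweeps are progressively invisible at this scale |

`simulate_four_pops()` generates replicate four-population cohorts for the
f4 machinery by pure frequency drift (binomial Wright–Fisher steps down a
bifurcating tree, no linkage), which is exactly the independence null the
block jackknife is calibrated against; an optional admixture pulse mixes a
fraction of one population's gene pool into another. `generate_resources()`
adds gene models (non-overlapping, with UTR/exon/intron/splice structure),
a preferential-attachment interaction network, random gene sets with
optional planted enrichment, and site scores with deleterious status
optionally planted on sites whose derived allele rose in the domestic
cohort. `write_dataset()`/`read_dataset()` round-trip everything through
standard formats (VCF, FASTA, GFF3, TSV, JSON truth manifest),
byte-identically for a fixed seed.

## What the generator does and does not emulate

It emulates: two diverged populations with realistic diversity contrast; a
single-origin hard sweep with a hitchhiking footprint, escape lineages and
post-sweep singleton excess; bottleneck-induced genome-wide LD structure
and growth-phase rare-variant excess; exact outgroup polarization; migration.

It does not emulate: deep coalescent LD in the standing pool (the pool is
seeded at linkage equilibrium, so background haplotype structure is built
only during the simulated episode — EHH decays faster, and background iHS
is better behaved, than in real data); variable recombination or mutation
rate along the genome; sequencing error, genotyping and phasing error
(inputs are true phased haplotypes); selection on standing variation or
soft sweeps. Passing power tests therefore demonstrate that the estimators
and the calling logic behave correctly on data whose generating process is
known — not that real cohorts of any particular species would yield the
same sensitivity.

# Numerical and design choices

* Internal coordinates are 0-based half-open; VCF positions are 1-based.
  A window contains a SNP when its 0-based position falls in
  `[start, end)`.
* Missing genotypes: frequency-based statistics adjust $n$ per site;
  haplotype statistics (EHH/iHS) and SFS tallies drop sites with any
  missing call, counting them.
* Quantile thresholds use the k-th order statistic with
  $k = \lceil q\,m \rceil$ over non-missing windows, ties included —
  deterministic and conservative.
* Windows with fewer than 2 SNPs are missing for D and H; empty windows are
  missing, never 0, for every statistic.
* The CLR lookup is tabulated on a uniform $\alpha d$ grid (481 nodes,
  linear interpolation), which resolves $p_e$ exponentially finely near 1
  so that distant sites contribute vanishing log-likelihood-ratio terms;
  probabilities are floored at $10^{-12}$ to keep logs finite. The focal
  site's own term (distance 0, $p_e = 0$, a degenerate point-mass
  distribution) is excluded from the composite product.
* The Hp shuffle assembles *non-overlapping* scan windows from consecutive
  shuffled 1-kb blocks (after permutation, overlap would add no
  information); an aggregation at the 1-kb level itself is available by
  setting `scan_window_blocks = 1`.
* iHS cores whose EHH reaches a chromosome end before decaying to 0.05 are
  flagged edge-truncated and excluded from standardization by default
  (their integrals are biased downward).
* `f4_ztest()` floors a collapsed jackknife SE at machine epsilon and flags
  the result degenerate rather than dividing by zero.
* Block-jackknife blocks are equal SNP-count, unweighted; the equal-block
  closed form $SD/\sqrt m$ is recovered exactly.
* The hub test's random sub-networks are summarised by the median rank at
  each sorted position across resamples, reproducing the published
  "median rank of 1000 samplings" construction.

## Open choices resolved

* Base/mapping-quality filters are applied per site on INFO aggregates
  (DP/BQ/MQ/AD), not per read; read-level data are out of scope.
* iHS standardization is genome-wide by default (`per-chromosome` can be
  obtained by scanning chromosomes separately); the derived-frequency bin
  width, unstated in the source protocol, defaults to 0.05.
* 1% method thresholds are genome-wide, not per chromosome.
* The iHS rescue rule (rule 4) is restricted to SNPs inside consensus
  sweeps.
* The burden chi-square contrasts derived *allele counts* by default;
  a site-count reading is available via `unit = "sites"`.
* Polarization for D is performed on the same unfolded tallies as for H
  ($\theta_\pi$ is folding-invariant, so only the $\theta_w$/$\theta_H$
  tallies depend on it).

# Problem sizes used by the test suite

The suite regenerates everything it tests: 20 replicate domestication
cohorts at the defaults above (shared across the consensus-recovery, iHS,
CLR and burden power tests), 20 neutral constant-size cohorts for
calibration (mean D and H within 3 Monte-Carlo SEs of 0 over 300+ windows;
paired wild/domestic diversity exchangeable), 200 replicate four-population
nulls of 5,000 unlinked SNPs with ~50 jackknife blocks (mean Z within 3 MC
SEs of 0; variance of Z in [0.7, 1.3]), 200-trial calibrations of the hub
and set-enrichment P values against uniformity, 500 uniform-placement
replicates for the region-enrichment type-I rate, and exhaustive oracle
enumerations (all 2×2 tables to N = 50; all escape configurations to
n = 8).

# Known limitations

* The CLR scan, as specified — segregating sites only, with the swept
  haplotype carrying the ancestral allele — cannot exploit the diversity
  wipe-out itself, and under a bottleneck-plus-growth background (whose SFS
  is already singleton-rich) its genome-wide maximum localises the sweep in
  only a minority of desk-scale replicates. It remains a useful *consensus
  member* (sweep windows carry systematically higher CLR than background,
  which the suite asserts), but it is the weakest of the five methods at
  this scale.
* Fay & Wu's H loses its signal once a sweep fixes (the high-frequency
  derived class collapses into invisible fixed differences); it
  contributes most in replicates sampled mid-sweep.
* iHS has little window-level power on the generator's cohorts at this
  scale: near-fixed cores are monomorphic or fall in sparse
  derived-frequency bins, and the founding bottleneck gives *all*
  haplotypes long shared tracts, compressing the sweep/background EHH
  contrast. The per-SNP mechanism (a long shared derived haplotype drives
  `ln(iHH_A/iHH_D)` strongly negative) is verified on constructed
  partial-sweep fixtures instead; `sweep$min_final_freq`/`max_final_freq`
  in `sim_config()` let users generate mid-sweep cohorts.
* With 49 windows per genome, the bottommost-1% rule flags a single window
  per method, so consensus demands near-exact co-localisation of two
  methods' extremes; at genome scale (thousands of windows) the same rules
  flag broad multi-window valleys and are considerably more forgiving.
* `omega_per_individual()` currently handles plus-strand, single-segment
  CDS models — sufficient for generated data; real annotations need
  splicing-aware CDS extraction upstream.
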