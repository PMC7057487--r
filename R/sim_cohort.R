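#' Simulation configuration
#'
#' Defaults describe a desk-scale domestication scenario: a wild and a
#' domestic population of effective size `N` split `split_gens` generations
#' ago from a common equilibrium pool; the domestic lineage passes a
#' founding bottleneck and (optionally) experiences a hard sweep from
#' standing variation plus migration. Rates are inflated relative to real
#' genomes so that a 1-Mb genome carries a workable number of SNPs.
#'
#' @param seed RNG seed (mandatory).
#' @param n_wild,n_domestic diploid sample sizes drawn at the end.
#' @param N diploid effective size of each population.
#' @param L genome length in bp.
#' @param mu per-bp per-generation mutation rate.
#' @param r per-bp per-generation recombination rate.
#' @param split_gens generations since the wild/domestic split.
#' @param bottleneck list `factor` (size multiplier) and `duration`
#'   (generations at reduced size, starting at the split), or `NULL`.
#' @param sweep list `position`, `s` (selection coefficient per derived
#'   copy), `start_gen` (generation of the domestic epoch in which the
#'   beneficial mutation arises; selection acts from then on) and
#'   `initial_copies` (founder haplotype copies, default 1 = hard sweep of
#'   single origin), or `NULL` for neutrality. Optional `min_final_freq`
#'   (default 0.95) and `max_final_freq` (default 1) condition the restart
#'   rule on the derived frequency at sampling time — e.g. a range of
#'   \[0.5, 0.95) yields cohorts sampled mid-sweep.
#' @param migration list `source`, `dest` ("wild"/"domestic"), `rate`
#'   (fraction of destination haplotypes replaced per generation),
#'   `start_gen`, `duration`, or `NULL`.
#' @param outgroup_divergence substitutions per bp separating the outgroup
#'   from the ancestral sequence.
#' @param max_restarts restart cap for sweep establishment.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed, n_wild = 10, n_domestic = 10, N = 200, L = 1e6,
                       mu = 4e-7, r = 2e-7, split_gens = 100,
                       bottleneck = list(factor = 0.1, duration = 20),
                       sweep = list(position = 5e5, s = 0.05, start_gen = 1,
                                    initial_copies = 1),
                       migration = NULL, outgroup_divergence = 0.02,
                       max_restarts = 100) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (!is.null(sweep) && sweep$position >= L) stop("sweep position must be < L")
  stopifnot(mu >= 0, r >= 0, N >= 2, L > 0)
  structure(list(seed = seed, n_wild = n_wild, n_domestic = n_domestic, N = N,
                 L = L, mu = mu, r = r, split_gens = split_gens,
                 bottleneck = bottleneck, sweep = sweep, migration = migration,
                 outgroup_divergence = outgroup_divergence,
                 max_restarts = max_restarts), class = "sim_config")
}

# one Wright-Fisher generation for a haplotype matrix (rows = 2N haplotypes,
# columns = sites in a shared column space). Returns the offspring matrix
# plus new private mutation descriptors (positions + carrier rows).
wf_generation <- function(H, positions, n_next, mu, r, L, sel_col = NA,
                          s = 0) {
  n_cur <- nrow(H) / 2L
  w <- rep(1, n_cur)
  if (!is.na(sel_col) && s != 0) {
    copies <- H[seq(1, 2 * n_cur, by = 2), sel_col] + H[seq(2, 2 * n_cur, by = 2), sel_col]
    w <- (1 + s)^copies
  }
  n_gam <- 2L * n_next
  pid <- sample.int(n_cur, n_gam, replace = TRUE, prob = w)
  rc <- rpois(n_gam, r * L)
  start <- rbinom(n_gam, 1L, 0.5)
  Hn <- H[2L * pid - 1L + start, , drop = FALSE]
  for (i in which(rc > 0)) {
    bp <- sort(runif(rc[i], 0, L))
    parity <- findInterval(positions, bp) %% 2L
    swap <- parity == 1L
    if (any(swap)) Hn[i, swap] <- H[2L * pid[i] - 1L + (1L - start[i]), swap]
  }
  k <- rpois(1, n_gam * mu * L)
  new_pos <- integer(0); new_carrier <- integer(0)
  if (k > 0) {
    cand <- sample.int(L, k)
    cand <- cand[!(cand %in% positions)]
    if (length(cand) > 0) {
      new_pos <- cand
      new_carrier <- sample.int(n_gam, length(cand), replace = TRUE)
    }
  }
  list(H = Hn, new_pos = new_pos, new_carrier = new_carrier)
}

#' Simulate a wild/domestic cohort by forward Wright-Fisher simulation
#'
#' Both populations descend from a shared standing-variation pool at
#' mutation-drift equilibrium (population SFS proportional to 1/i, alleles
#' assigned to haplotypes at linkage equilibrium) and then evolve forward
#' with recombination, mutation and, for the domestic lineage, a founding
#' bottleneck and an optional hard sweep from standing variation. The sweep
#' is conditioned on establishment (derived frequency >= 0.95 at sampling
#' time) by restarting up to `max_restarts` times; exceeding the cap is an
#' error.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_cohort` with `gt` (combined
#'   [genotype_table()], populations "wild"/"domestic"), `ancestral_seq`
#'   and `outgroup_seq` (character vectors of length `L`), `truth` (sweep
#'   locus and final frequency, restart count, migration, fixed
#'   substitutions, per-site ancestral allele coding) and `config`.
#' @export
simulate_cohort <- function(cfg) {
  with_seed(cfg$seed, {
    N <- cfg$N; L <- cfg$L
    # equilibrium standing variation: E[#sites at count i] = theta*L/i
    i_max <- 2L * N - 1L
    exp_S <- 4 * N * cfg$mu * L * sum(1 / seq_len(i_max))
    S0 <- rpois(1, exp_S)
    S0 <- min(S0, L - 1L)
    positions <- sort(sample.int(L, S0))
    counts <- sample.int(i_max, S0, replace = TRUE, prob = 1 / seq_len(i_max))
    H0 <- matrix(0L, nrow = 2L * N, ncol = S0)
    for (j in seq_len(S0)) H0[sample.int(2L * N, counts[j]), j] <- 1L

    dom_sizes <- rep(N, cfg$split_gens)
    if (!is.null(cfg$bottleneck)) {
      dur <- min(cfg$bottleneck$duration, cfg$split_gens)
      dom_sizes[seq_len(dur)] <- max(2L, round(N * cfg$bottleneck$factor))
    }

    run_episode <- function() {
      pos <- positions
      W <- H0; D <- H0
      sweep_col <- NA_integer_
      if (!is.null(cfg$sweep)) {
        sp <- as.integer(cfg$sweep$position)
        while (sp %in% pos) sp <- sp + 1L
        pos <- c(pos, sp)
        W <- cbind(W, 0L)
        D <- cbind(D, 0L)
        sweep_col <- length(pos)
      }
      fixed_pos <- integer(0)
      traj <- rep(NA_real_, cfg$split_gens)
      for (g in seq_len(cfg$split_gens)) {
        sel_on <- !is.null(cfg$sweep) && g > cfg$sweep$start_gen
        gw <- wf_generation(W, pos, N, cfg$mu, cfg$r, L)
        gd <- wf_generation(D, pos, dom_sizes[g], cfg$mu, cfg$r, L,
                            sel_col = if (sel_on) sweep_col else NA,
                            s = if (sel_on) cfg$sweep$s else 0)
        W <- gw$H; D <- gd$H
        # append each population's new mutations to the shared column space,
        # dropping same-generation position collisions between the two pools
        if (length(gd$new_pos) > 0 && length(gw$new_pos) > 0) {
          clash <- gd$new_pos %in% gw$new_pos
          gd$new_pos <- gd$new_pos[!clash]
          gd$new_carrier <- gd$new_carrier[!clash]
        }
        n_new <- length(gw$new_pos) + length(gd$new_pos)
        if (n_new > 0) {
          newW <- matrix(0L, nrow(W), n_new)
          newD <- matrix(0L, nrow(D), n_new)
          if (length(gw$new_pos) > 0)
            newW[cbind(gw$new_carrier, seq_along(gw$new_pos))] <- 1L
          if (length(gd$new_pos) > 0)
            newD[cbind(gd$new_carrier, length(gw$new_pos) + seq_along(gd$new_pos))] <- 1L
          W <- cbind(W, newW); D <- cbind(D, newD)
          pos <- c(pos, gw$new_pos, gd$new_pos)
        }
        if (!is.null(cfg$sweep) && g == cfg$sweep$start_gen) {
          # the beneficial mutation arises among generation start_gen's offspring
          nh <- nrow(D)
          k0 <- min(nh, max(1L, cfg$sweep$initial_copies %||% 1L))
          D[, sweep_col] <- 0L
          D[sample.int(nh, k0), sweep_col] <- 1L
        }
        if (!is.null(cfg$migration)) {
          mg <- cfg$migration
          if (g > mg$start_gen && g <= mg$start_gen + mg$duration) {
            src <- if (mg$source == "wild") W else D
            n_dst <- if (mg$dest == "wild") nrow(W) else nrow(D)
            n_mig <- round(mg$rate * n_dst)
            if (n_mig > 0) {
              repl <- sample.int(n_dst, n_mig)
              from <- sample.int(nrow(src), n_mig, replace = TRUE)
              if (mg$dest == "wild") W[repl, ] <- src[from, , drop = FALSE]
              else D[repl, ] <- src[from, , drop = FALSE]
            }
          }
        }
        # early abort if the selected allele is lost after implantation
        if (!is.na(sweep_col) && g >= cfg$sweep$start_gen) {
          traj[g] <- mean(D[, sweep_col])
          if (traj[g] == 0) return(NULL)
        }
        if (g %% 20L == 0L || g == cfg$split_gens) {
          cw <- colSums(W); cd <- colSums(D)
          lost <- cw == 0L & cd == 0L
          both_fixed <- cw == nrow(W) & cd == nrow(D)
          if (!is.na(sweep_col)) { lost[sweep_col] <- FALSE; both_fixed[sweep_col] <- FALSE }
          fixed_pos <- c(fixed_pos, pos[both_fixed])
          drop <- lost | both_fixed
          if (any(drop)) {
            if (!is.na(sweep_col)) sweep_col <- sweep_col - sum(drop[seq_len(sweep_col - 1L)])
            W <- W[, !drop, drop = FALSE]; D <- D[, !drop, drop = FALSE]
            pos <- pos[!drop]
          }
        }
      }
      if (!is.na(sweep_col)) {
        freq <- mean(D[, sweep_col])
        if (freq < (cfg$sweep$min_final_freq %||% 0.95) ||
            freq > (cfg$sweep$max_final_freq %||% 1)) return(NULL)
      }
      list(W = W, D = D, pos = pos, sweep_col = sweep_col,
           fixed_pos = fixed_pos, traj = traj)
    }

    ep <- NULL; restarts <- 0L
    repeat {
      ep <- run_episode()
      if (!is.null(ep)) break
      restarts <- restarts + 1L
      if (restarts > cfg$max_restarts)
        stop("sweep lost by drift after ", restarts, " restarts")
    }

    # sample diploids
    wi <- sample.int(N, cfg$n_wild)
    di <- sample.int(N, cfg$n_domestic)
    Wr <- ep$W[as.vector(rbind(2L * wi - 1L, 2L * wi)), , drop = FALSE]
    Dr <- ep$D[as.vector(rbind(2L * di - 1L, 2L * di)), , drop = FALSE]
    hap <- rbind(Wr, Dr)
    seg <- colSums(hap) > 0L  # variant relative to the ancestral reference
    hap <- hap[, seg, drop = FALSE]
    pos <- ep$pos[seg]
    ord <- order(pos)
    hap <- hap[, ord, drop = FALSE]
    pos <- pos[ord]

    anc_seq <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    ref <- anc_seq[pos]
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    outgroup <- anc_seq
    n_div <- rpois(1, cfg$outgroup_divergence * L)
    if (n_div > 0) {
      dpos <- sample.int(L, min(n_div, L))
      dpos <- setdiff(dpos, pos)  # outgroup keeps the ancestral allele at SNPs
      outgroup[dpos] <- vapply(outgroup[dpos],
                               function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    }
    samples <- data.frame(
      sample = c(paste0("wild_", seq_len(cfg$n_wild)),
                 paste0("dom_", seq_len(cfg$n_domestic))),
      population = c(rep("wild", cfg$n_wild), rep("domestic", cfg$n_domestic)),
      stringsAsFactors = FALSE)
    gt <- genotype_table(hap, pos, "1", ref, alt, samples, phased = TRUE)
    sweep_truth <- NULL
    if (!is.null(cfg$sweep)) {
      sc_pos <- ep$pos[ep$sweep_col]
      sweep_truth <- list(position = sc_pos,
                          s = cfg$sweep$s,
                          final_freq_domestic = mean(ep$D[, ep$sweep_col]),
                          fixed = mean(ep$D[, ep$sweep_col]) == 1,
                          trajectory = ep$traj,
                          # conservative hitchhiking interval: the footprint
                          # scale 1/(r * sum(1 - p)) exceeds 50 kb at defaults
                          interval = c(max(0, sc_pos - 50000),
                                       min(L, sc_pos + 50000)))
    }
    truth <- list(sweep = sweep_truth, restarts = restarts,
                  migration = cfg$migration,
                  fixed_substitutions = sort(ep$fixed_pos),
                  ancestral = rep("ref", length(pos)),
                  seed = cfg$seed)
    structure(list(gt = gt, ancestral_seq = anc_seq, outgroup_seq = outgroup,
                   truth = truth, config = cfg), class = "sim_cohort")
  })
}

#' Simulate replicate four-population cohorts by frequency drift
#'
#' Allele frequencies start from the equilibrium spectrum of an ancestral
#' population and drift down a bifurcating tree ((A,B),(C,D)) by binomial
#' Wright-Fisher sampling with no linkage; sample frequencies are then drawn
#' for `n_per_pop` diploids per population. An optional admixture pulse
#' mixes a fraction of one population's gene pool into another after the
#' drift phase, violating the tree.
#'
#' @param n_snps number of unlinked SNPs.
#' @param N diploid population size for the drift steps (default 200).
#' @param n_per_pop diploid sample size per population (default 10).
#' @param t_internal generations of drift from the root to the two internal
#'   ancestors (default 40).
#' @param t_tip generations of drift from each internal ancestor to its two
#'   tips (default 40).
#' @param migration `NULL`, or list `source`, `dest` (population letters)
#'   and `rate` (admixture fraction).
#' @param seed RNG seed (required).
#' @return list with `freqs` (data.frame `pA..pD` of sample frequencies in
#'   genome order), `positions`, and `truth`.
#' @export
simulate_four_pops <- function(n_snps = 5000, N = 200, n_per_pop = 10,
                               t_internal = 40, t_tip = 40, migration = NULL,
                               seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  with_seed(seed, {
    i_max <- 2L * N - 1L
    p0 <- sample.int(i_max, n_snps, replace = TRUE, prob = 1 / seq_len(i_max)) / (2 * N)
    drift <- function(p, t) {
      for (g in seq_len(t)) p <- rbinom(length(p), 2L * N, p) / (2 * N)
      p
    }
    pAB <- drift(p0, t_internal); pCD <- drift(p0, t_internal)
    pop <- list(A = drift(pAB, t_tip), B = drift(pAB, t_tip),
                C = drift(pCD, t_tip), D = drift(pCD, t_tip))
    if (!is.null(migration)) {
      m <- migration$rate
      pop[[migration$dest]] <- (1 - m) * pop[[migration$dest]] + m * pop[[migration$source]]
    }
    nh <- 2L * n_per_pop
    samp <- lapply(pop, function(p) rbinom(length(p), nh, p) / nh)
    freqs <- data.frame(pA = samp$A, pB = samp$B, pC = samp$C, pD = samp$D)
    list(freqs = freqs, positions = seq_len(n_snps) * 500L,
         truth = list(migration = migration, N = N, t_internal = t_internal,
                      t_tip = t_tip, seed = seed))
  })
}
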