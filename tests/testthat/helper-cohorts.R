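# Shared simulated cohorts, generated once per test run and reused across
# test files (simulation is the dominant cost of the suite).

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cohort_cache)) assign(key, force(expr), envir = .cohort_cache)
  get(key, envir = .cohort_cache)
}

# 20 replicate domestication cohorts at generator defaults (hard sweep +
# bottleneck), each with the full five-method scan of the domestic cohort
sweep_bundles <- function(n = 20) {
  cached(paste0("sweep", n), lapply(seq_len(n), function(i) {
    sim <- simulate_cohort(sim_config(seed = i))
    anc <- rep("ref", n_sites(sim$gt))
    sc <- scan_cohort(sim$gt, anc, "domestic", c("1" = sim$config$L),
                      seed = 1000 + i)
    list(sim = sim, anc = anc, scan = sc)
  }))
}

# neutral constant-size cohorts (no sweep, no bottleneck)
neutral_sims <- function(n = 20) {
  cached(paste0("neutral", n), lapply(seq_len(n), function(i) {
    simulate_cohort(sim_config(seed = 600 + i, bottleneck = NULL, sweep = NULL))
  }))
}

# toy deterministic genotype table builder
toy_gt <- function(hap, positions = NULL, pops = NULL) {
  hap <- as.matrix(hap)
  if (is.null(positions)) positions <- seq_len(ncol(hap)) * 100L
  n_samp <- nrow(hap) / 2
  samples <- data.frame(
    sample = paste0("s", seq_len(n_samp)),
    population = pops %||% rep("pop1", n_samp),
    stringsAsFactors = FALSE)
  genotype_table(hap, positions, "1", rep("A", ncol(hap)), rep("G", ncol(hap)),
                 samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
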