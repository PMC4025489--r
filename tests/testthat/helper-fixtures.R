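# Small fixtures built in code; sizes chosen so the full suite stays fast.

# A well-differentiated founder pair at desk scale.
tiny_freqs <- function(n_loci = 600, fst = 0.1, seed = 101) {
  gen_founder_frequencies(n_loci, fst, seed = seed)
}

# A reduced three-group study population (same structure as the full one).
tiny_population <- function(n_loci = 600, seed = 202) {
  cfg <- default_config()
  cfg$population$n_loci <- as.integer(n_loci)
  cfg$population$n_admix_founders <- 25L
  cfg$population$n_unmixed_founders <- c(19L, 25L)
  cfg$population$n_unmixed <- c(50L, 50L)
  cfg$population$n_admixed <- 150L
  cfg$population$n_generations <- 4L
  freqs <- tiny_freqs(n_loci, seed = seed)
  assemble_study_population(freqs, cfg, seed = seed + 1)
}

# Deterministic toy genotype table.
toy_genotypes <- function() {
  genotype_table(rbind(
    c(0L, 0L, 1L),
    c(2L, 2L, 1L),
    c(1L, 0L, 9L)
  ), c("a", "b", "c"), c("L1", "L2", "L3"))
}

# A cohort of unmixed individuals from two fixed-frequency populations.
toy_cohort <- function(n = 6, m = 20, seed = 7) {
  withr::with_seed(seed, {
    g1 <- matrix(rbinom(n * m / 2, 2, 0.1), n / 2, m)
    g2 <- matrix(rbinom(n * m / 2, 2, 0.9), n / 2, m)
  })
  ids <- paste0("i", seq_len(n))
  gt <- genotype_table(rbind(g1, g2), ids)
  lb <- label_table(ids, rep(1:2, each = n / 2), rep(c(0, 1), each = n / 2))
  cohort(gt, lb)
}
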