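test_that("founder frequencies follow the Balding-Nichols model", {
  f <- gen_founder_frequencies(5000, 0.1, seed = 1)
  expect_s3_class(f, "founder_freqs")
  expect_true(all(f$ancestral_freq >= 0.05 & f$ancestral_freq <= 0.95))
  expect_true(all(f$pop_freq > 0 & f$pop_freq < 1))  # monomorphic rejected
  # Beta mean equals the ancestral frequency: average deviation ~ 0 over loci
  dev <- colMeans(f$pop_freq) - f$ancestral_freq
  expect_lt(abs(mean(dev)), 3 * sd(dev) / sqrt(length(dev)))
  # near-zero drift collapses both populations onto the ancestral frequency
  f0 <- gen_founder_frequencies(200, 1e-4, seed = 2)
  expect_lt(max(abs(t(f0$pop_freq) - f0$ancestral_freq)), 0.05)
  expect_error(gen_founder_frequencies(100, 0.6), "fst_target")
  expect_error(gen_founder_frequencies(100, 0), "fst_target")
  # per-population drift pair is accepted and recorded
  f2 <- gen_founder_frequencies(100, drift_f = c(0.05, 0.13), seed = 3)
  expect_equal(f2$drift_f, c(0.05, 0.13))
})

test_that("differentiation calibration holds across seeds", {
  fst <- vapply(1:30, function(s) {
    f <- gen_founder_frequencies(1500, 0.1, seed = 1000 + s)
    co <- sample_founder_genotypes(f, 50, seed = 2000 + s)
    hudson_fst(subset_cohort(co, 1:50), subset_cohort(co, 51:100))
  }, numeric(1))
  se <- sd(fst) / sqrt(length(fst))
  expect_lt(abs(mean(fst) - 0.1), 2 * se + 0.005)
})

test_that("founder genotypes are binomial draws from population frequencies", {
  f <- structure(list(
    ancestral_freq = c(0.5, 0.5, 0.5),
    pop_freq = rbind(c(1, 0, 0.4), c(0, 1, 0.8)),
    drift_f = c(0.1, 0.1)
  ), class = "founder_freqs")
  co <- sample_founder_genotypes(f, 40, seed = 4)
  g <- co$genotypes$matrix
  expect_true(all(g[1:40, 1] == 2L))   # fixed alternate in population 1
  expect_true(all(g[1:40, 2] == 0L))
  expect_true(all(g[41:80, 1] == 0L))
  expect_true(all(g[41:80, 2] == 2L))
  # sample frequency within binomial error of the truth
  expect_lt(abs(mean(g[1:40, 3]) / 2 - 0.4), 3 * sqrt(0.4 * 0.6 / 80))
  expect_equal(co$labels$group, rep(1:2, each = 40))
  expect_equal(co$labels$true_theta, rep(c(0, 1), each = 40))
  expect_error(sample_founder_genotypes(f, 0), "n_per_pop")
})

test_that("one admixture generation gives theta exactly one half", {
  f <- tiny_freqs(50)
  co <- sample_founder_genotypes(f, 10, seed = 5)
  adm <- simulate_admixture(subset_cohort(co, 1:10)$genotypes,
                            subset_cohort(co, 11:20)$genotypes,
                            n_offspring = 40, n_generations = 1, seed = 6)
  expect_true(all(adm$labels$true_theta == 0.5))
  expect_equal(n_individuals(adm), 40)
  expect_true(all(adm$labels$group == 3L))
})

test_that("without recombination haplotypes transmit whole", {
  f <- tiny_freqs(50)
  co <- sample_founder_genotypes(f, 10, seed = 7)
  adm <- simulate_admixture(subset_cohort(co, 1:10)$genotypes,
                            subset_cohort(co, 11:20)$genotypes,
                            n_offspring = 60, n_generations = 2,
                            recomb_rate = 0, seed = 8)
  # each gamete is an intact generation-1 haplotype: quarter-steps only
  expect_true(all(adm$labels$true_theta %in% c(0, 0.25, 0.5, 0.75, 1)))
  # and each haplotype carries a single un-recombined ancestry segment
  seg_counts <- vapply(adm$segments, function(s) {
    max(nrow(s[[1]]), nrow(s[[2]]))
  }, numeric(1))
  expect_true(all(seg_counts == 1))
})

test_that("theta equals the segment-derived population-2 fraction", {
  f <- tiny_freqs(80)
  co <- sample_founder_genotypes(f, 8, seed = 9)
  adm <- simulate_admixture(subset_cohort(co, 1:8)$genotypes,
                            subset_cohort(co, 9:16)$genotypes,
                            n_offspring = 30, n_generations = 5, seed = 10)
  L <- 1.02e8
  recomputed <- vapply(seq_len(30), function(i) {
    s <- adm$segments[[i]]
    tot <- 0
    for (h in s) tot <- tot + sum((h$end - h$start)[h$pop == 2L])
    tot / (2 * L)
  }, numeric(1))
  expect_equal(adm$labels$true_theta, recomputed, tolerance = 1e-12)
  # segments tile the region exactly on both haplotypes
  for (i in 1:5) {
    for (h in adm$segments[[i]]) {
      expect_equal(sum(h$end - h$start), L)
      expect_true(all(h$start >= 0 & h$end <= L))
    }
  }
})

test_that("simulation is reproducible and mixing reduces theta spread", {
  f <- tiny_freqs(30)
  co <- sample_founder_genotypes(f, 10, seed = 11)
  g1 <- subset_cohort(co, 1:10)$genotypes
  g2 <- subset_cohort(co, 11:20)$genotypes
  a <- simulate_admixture(g1, g2, 50, 4, seed = 12)
  b <- simulate_admixture(g1, g2, 50, 4, seed = 12)
  expect_identical(a$genotypes$matrix, b$genotypes$matrix)
  expect_identical(a$labels$true_theta, b$labels$true_theta)

  # variance of theta shrinks (on average) as random mating continues
  vdiff <- vapply(1:30, function(s) {
    early <- simulate_admixture(g1, g2, 80, 2, seed = 300 + s)
    late <- simulate_admixture(g1, g2, 80, 7, seed = 600 + s)
    var(early$labels$true_theta) - var(late$labels$true_theta)
  }, numeric(1))
  expect_gt(mean(vdiff), -1e-4)
})

test_that("pool expansion duplicates cyclically", {
  co <- toy_cohort(n = 6, m = 10)
  p1 <- subset_cohort(co, 1:3)
  # identity when the target equals the current size
  same <- expand_pool(p1, 3)
  expect_identical(same$genotypes$matrix[, ], p1$genotypes$matrix[, ])
  # n -> 2n duplicates every individual exactly once
  doubled <- expand_pool(p1, 6)
  expect_equal(as.integer(table(doubled$provenance)), rep(2L, 3))
  expect_error(expand_pool(p1, 2), "target_count")

  # 38 founders to 100: 24 triplicated, 14 duplicated
  ids <- paste0("f", 1:38)
  gt <- genotype_table(matrix(0L, 38, 4), ids)
  lb <- label_table(ids, rep(1L, 38), rep(0, 38))
  big <- expand_pool(cohort(gt, lb), 100)
  counts <- table(big$provenance)
  expect_equal(n_individuals(big), 100)
  expect_equal(sum(counts == 3), 24)
  expect_equal(sum(counts == 2), 14)
})

test_that("the assembled study population has the configured structure", {
  pop <- tiny_population(n_loci = 200)
  expect_equal(n_individuals(pop), 250)
  expect_equal(as.integer(table(pop$labels$group)), c(50L, 50L, 150L))
  th <- pop$labels$true_theta
  u <- pop$labels$group
  expect_true(all(th[u == 1] == 0))
  expect_true(all(th[u == 2] == 1))
  expect_true(all(th[u == 3] > 0 & th[u == 3] < 1))
  # groups concatenated in canonical order
  expect_equal(u, rep(c(1L, 2L, 3L), c(50, 50, 150)))
  # bit-reproducible under a fixed seed
  cfg <- default_config()
  cfg$population$n_loci <- 200L
  cfg$population$n_admix_founders <- 25L
  cfg$population$n_unmixed_founders <- c(19L, 25L)
  cfg$population$n_unmixed <- c(50L, 50L)
  cfg$population$n_admixed <- 150L
  cfg$population$n_generations <- 4L
  freqs <- tiny_freqs(200, seed = 202)
  again <- assemble_study_population(freqs, cfg, seed = 203)
  expect_identical(pop$genotypes$matrix, again$genotypes$matrix)
  expect_identical(pop$labels$true_theta, again$labels$true_theta)
})
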