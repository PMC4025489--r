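# Reduced-scale experiment configuration shared across these tests.
tiny_cfg <- function() {
  cfg <- default_config()
  cfg$population$n_loci <- 300L
  cfg$population$n_admix_founders <- 25L
  cfg$population$n_unmixed_founders <- c(19L, 25L)
  cfg$population$n_unmixed <- c(50L, 50L)
  cfg$population$n_admixed <- 150L
  cfg$population$n_generations <- 4L
  cfg$grid$x <- c(10L, 25L)
  cfg$grid$y <- c(10L, 50L)
  cfg$grid$replicates <- 2L
  cfg$inference$tol <- 1e-2
  cfg$inference$max_iter <- 300L
  cfg
}

test_that("duplicate collapsing is lossless", {
  pop <- tiny_population(n_loci = 80)
  s <- draw_biased_sample(pop, sample_spec(10, 60, 10), seed = 91)
  col <- collapse_duplicates(s)
  expect_equal(sum(col$counts), n_individuals(s))
  expect_equal(length(col$counts), n_individuals(col$cohort))
  # expansion reconstructs the original rows exactly
  expect_equal(unname(col$cohort$genotypes$matrix[col$expand, ]),
               unname(s$genotypes$matrix))
  expect_equal(col$cohort$labels$true_theta[col$expand],
               s$labels$true_theta)
  expect_identical(col$cohort$provenance[col$expand], s$provenance)
})

test_that("a single-cell run is deterministic under a fixed seed", {
  cfg <- tiny_cfg()
  cfg$grid$x <- 15L
  cfg$grid$y <- 30L
  cfg$grid$replicates <- 1L
  pop <- tiny_population(n_loci = 300)
  a <- run_grid_experiment(cfg, population = pop, seed = 5)
  b <- run_grid_experiment(cfg, population = pop, seed = 5)
  expect_identical(a$results, b$results)
  expect_equal(nrow(a$results), 1)
  expect_false(is.na(a$results$r2))
})

test_that("the grid runner covers cells, corrections and aggregation", {
  cfg <- tiny_cfg()
  pop <- tiny_population(n_loci = 300)
  tab <- run_grid_experiment(cfg, population = pop, seed = 6)
  expect_s3_class(tab, "result_table")
  expect_equal(nrow(tab$results), 4 * 2)   # cells x replicates
  expect_equal(nrow(tab$aggregate), 4)
  expect_true(all(c("mean", "se", "tau") %in% names(tab$aggregate)))
  expect_true(all(tab$results$r2 >= 0 & tab$results$r2 <= 1, na.rm = TRUE))
  # balanced cells recover ancestry well even at this tiny scale
  bal <- tab$aggregate[tab$aggregate$x == 25 & tab$aggregate$y == 10, ]
  expect_gt(bal$mean, 0.8)

  cfg$correction$mode <- "resample"
  tabr <- run_grid_experiment(cfg, population = pop, seed = 6)
  expect_equal(unique(tabr$results$correction), "resample")
  expect_true(all(is.na(tabr$results$error)))

  cfg$correction$mode <- "weights"
  tabw <- run_grid_experiment(cfg, population = pop, seed = 6)
  expect_true(all(is.finite(tabw$results$r2)))
})

test_that("failing cells are recorded, not dropped", {
  cfg <- tiny_cfg()
  cfg$population$n_admixed <- 0L   # no admixed group exists
  cfg$grid$x <- 5L
  cfg$grid$y <- 5L
  cfg$grid$replicates <- 1L
  freqs <- tiny_freqs(100, seed = 303)
  pop <- assemble_study_population(freqs, cfg, seed = 304)
  tab <- run_grid_experiment(cfg, population = pop, seed = 7)
  expect_equal(nrow(tab$results), 1)
  expect_true(is.na(tab$results$r2))
  expect_match(tab$results$error, "group 3 absent")
})

test_that("tau scan reports a threshold within the scanned range", {
  cfg <- tiny_cfg()
  pop <- tiny_population(n_loci = 300)
  tab <- run_tau_scan(cfg, population = pop, taus = c(1, 4), x = 20, seed = 8)
  expect_equal(sort(tab$aggregate$tau), c(1, 4))
  thr <- attr(tab, "tau_threshold")
  expect_true(thr %in% c(0, 1, 4))
  # threshold estimation: synthetic aggregate with a known cutoff
  fake <- tab
  fake$aggregate$mean <- ifelse(fake$aggregate$tau == 1, 0.99, 0.80)
  expect_equal(estimate_tau_threshold(fake), 1)
  fake$aggregate$mean <- rep(0.2, 2)
  expect_equal(estimate_tau_threshold(fake), 0)
})

test_that("paired correction comparison is exactly paired", {
  cfg <- tiny_cfg()
  cfg$grid$x <- 10L
  cfg$grid$y <- c(10L, 50L)
  cfg$grid$replicates <- 2L
  pop <- tiny_population(n_loci = 300)
  cmp <- run_correction_comparison(cfg, population = pop, seed = 9)
  expect_equal(nrow(cmp), 4)
  expect_equal(cmp$delta, cmp$r2_corrected - cmp$r2_uncorrected)
  # the uncorrected arm must match an identically seeded plain grid run
  cfg$correction$mode <- "none"
  tab <- run_grid_experiment(cfg, population = pop, seed = 9)
  expect_equal(cmp$r2_uncorrected, tab$results$r2)
})

test_that("the bottleneck runner produces the expected sweep", {
  cfg <- default_config()
  cfg$population$n_loci <- 400L
  cfg$demography$alpha <- c(0.99, 0.1)
  cfg$demography$x_sweep <- c(5L, 25L)
  cfg$demography$n_sampled <- 25L
  cfg$demography$n_admixed <- 30L
  cfg$inference$tol <- 1e-2
  cfg$inference$max_iter <- 200L
  res <- run_bottleneck_experiment(cfg, correct = TRUE, replicates = 2,
                                   seed = 10)
  expect_equal(nrow(res), 2 * 2 * 2)
  expect_true(all(c("alpha", "x", "r2", "r2_corrected", "delta") %in%
                    names(res)))
  expect_true(all(is.finite(res$r2)))
  # more population-2 individuals never hurt much: r2 rises with x on average
  agg <- aggregate(r2 ~ alpha + x, res, mean)
  for (a in unique(agg$alpha)) {
    sub <- agg[agg$alpha == a, ]
    expect_gte(sub$r2[sub$x == 25], sub$r2[sub$x == 5] - 0.05)
  }
})
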