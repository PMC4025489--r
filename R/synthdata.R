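#' Balding-Nichols founder allele frequencies
#'
#' Generates two differentiated ancestral populations: ancestral frequencies
#' are drawn uniformly on `[0.05, 0.95]` and each population's frequency is
#' a Beta draw with mean equal to the ancestral frequency and dispersion set
#' by its drift coefficient `F` (the Balding-Nichols model), i.e.
#' `p_pop ~ Beta(p (1-F)/F, (1-p)(1-F)/F)`. With both drifts equal to `F`
#' the expected Hudson F_ST between large samples from the two populations
#' is approximately `F`. Loci that come out monomorphic in either population
#' are rejected and redrawn.
#'
#' @param n_loci Number of biallelic loci.
#' @param fst_target Differentiation target in (0, 0.5); used as the drift
#'   coefficient of both populations unless `drift_f` is given.
#' @param seed Optional integer seed.
#' @param drift_f Optional pair of per-population drift coefficients,
#'   allowing unequal effective sizes (see [demography_to_drift()]).
#' @return An object of class `founder_freqs` with fields `ancestral_freq`
#'   (length `n_loci`), `pop_freq` (2 x `n_loci`) and `drift_f`.
#' @examples
#' f <- gen_founder_frequencies(1000, fst_target = 0.1, seed = 1)
#' @export
gen_founder_frequencies <- function(n_loci, fst_target = 0.1, seed = NULL,
                                    drift_f = NULL) {
  if (n_loci < 1) stop("n_loci must be >= 1")
  if (is.null(drift_f)) {
    if (!is.numeric(fst_target) || fst_target <= 0 || fst_target >= 0.5) {
      stop("fst_target must lie in (0, 0.5)")
    }
    drift_f <- c(fst_target, fst_target)
  }
  if (length(drift_f) != 2 || any(drift_f <= 0) || any(drift_f >= 1)) {
    stop("drift_f must be two values in (0, 1)")
  }
  local_rng(seed)
  anc <- numeric(n_loci)
  pop <- matrix(NA_real_, 2, n_loci)
  todo <- seq_len(n_loci)
  while (length(todo) > 0) {
    a <- stats::runif(length(todo), 0.05, 0.95)
    p1 <- stats::rbeta(length(todo), a * (1 - drift_f[1]) / drift_f[1],
                       (1 - a) * (1 - drift_f[1]) / drift_f[1])
    p2 <- stats::rbeta(length(todo), a * (1 - drift_f[2]) / drift_f[2],
                       (1 - a) * (1 - drift_f[2]) / drift_f[2])
    anc[todo] <- a
    pop[1, todo] <- p1
    pop[2, todo] <- p2
    ok <- p1 > 0 & p1 < 1 & p2 > 0 & p2 < 1
    todo <- todo[!ok]
  }
  structure(list(ancestral_freq = anc, pop_freq = pop, drift_f = drift_f),
            class = "founder_freqs")
}

#' @export
print.founder_freqs <- function(x, ...) {
  cat(sprintf(
    "founder_freqs: %d loci, drift F = (%.4g, %.4g)\n",
    length(x$ancestral_freq), x$drift_f[1], x$drift_f[2]
  ))
  invisible(x)
}

#' Sample unmixed founder genotypes
#'
#' Draws diploid genotypes `Binomial(2, p)` per locus from each ancestral
#' population's allele frequencies. Population-1 individuals get group
#' label 1 and true theta 0; population-2 individuals label 2 and theta 1.
#'
#' @param freqs A [gen_founder_frequencies()] result.
#' @param n_per_pop Individuals per population (scalar, or a pair for
#'   unequal samples).
#' @param seed Optional integer seed.
#' @return A [cohort()] of `sum(n_per_pop)` unmixed individuals
#'   (population 1 first).
#' @export
sample_founder_genotypes <- function(freqs, n_per_pop, seed = NULL) {
  stopifnot(inherits(freqs, "founder_freqs"))
  if (length(n_per_pop) == 1) n_per_pop <- rep(n_per_pop, 2)
  if (any(n_per_pop < 1)) stop("n_per_pop must be >= 1")
  local_rng(seed)
  m <- length(freqs$ancestral_freq)
  draw <- function(n, p, prefix) {
    g <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
    genotype_table(g, paste0(prefix, seq_len(n)))
  }
  g1 <- draw(n_per_pop[1], freqs$pop_freq[1, ], "pop1_")
  g2 <- draw(n_per_pop[2], freqs$pop_freq[2, ], "pop2_")
  ids <- c(rownames(g1$matrix), rownames(g2$matrix))
  gt <- genotype_table(rbind(g1$matrix, g2$matrix), ids)
  lb <- label_table(ids, rep(1:2, n_per_pop), rep(c(0, 1), n_per_pop))
  cohort(gt, lb)
}

# Evenly spaced locus positions over [0, L) (bp, 0-based midpoints).
locus_positions <- function(n_loci, region_length_bp) {
  (seq_len(n_loci) - 0.5) * region_length_bp / n_loci
}

# Split unmixed diploid genotypes into phased haplotypes; heterozygote phase
# is randomized (phase only affects linkage, not the marginal model the
# inference assumes).
split_haplotypes <- function(g) {
  n <- nrow(g); m <- ncol(g)
  h1 <- matrix(0L, n, m)
  h1[g == 2L] <- 1L
  het <- g == 1L
  coin <- matrix(stats::runif(n * m) < 0.5, n, m) & het
  h1[het & coin] <- 1L
  h2 <- g - h1
  list(h1 = h1, h2 = h2)
}

# One meiosis: recombine the parent's two haplotypes into a gamete.
# Returns the gamete allele vector and its ancestry segments.
make_gamete <- function(hapA, hapB, segA, segB, pos, L, recomb_rate,
                        mutation_rate) {
  n_cross <- stats::rpois(1, L * recomb_rate)
  breaks <- if (n_cross > 0) sort(stats::runif(n_cross, 0, L)) else numeric(0)
  start <- sample.int(2L, 1L)  # which haplotype leads
  seg_idx <- findInterval(pos, breaks)          # 0-based chunk index
  use_A <- ((seg_idx + start) %% 2L) == 0L
  allele <- hapB
  allele[use_A] <- hapA[use_A]
  # ancestry segments: clip the source haplotype's segments to each chunk
  pts <- c(0, breaks, L)
  out <- vector("list", length(pts) - 1)
  for (k in seq_len(length(pts) - 1)) {
    src <- if (((k - 1L + start) %% 2L) == 0L) segA else segB
    lo <- pts[k]; hi <- pts[k + 1]
    keep <- src$end > lo & src$start < hi
    if (any(keep)) {
      s <- src[keep, , drop = FALSE]
      s$start <- pmax(s$start, lo)
      s$end <- pmin(s$end, hi)
      out[[k]] <- s
    }
  }
  seg <- do.call(rbind, out)
  seg <- merge_segments(seg)
  if (mutation_rate > 0) {
    n_mut <- stats::rbinom(1, length(allele), mutation_rate)
    if (n_mut > 0) {
      at <- sample.int(length(allele), n_mut)
      allele[at] <- 1L - allele[at]
    }
  }
  list(allele = allele, seg = seg)
}

merge_segments <- function(seg) {
  if (is.null(seg) || nrow(seg) <= 1) return(seg)
  seg <- seg[order(seg$start), , drop = FALSE]
  keep_rows <- list(seg[1, ])
  for (i in 2:nrow(seg)) {
    last <- keep_rows[[length(keep_rows)]]
    cur <- seg[i, ]
    if (cur$pop == last$pop && cur$start <= last$end) {
      last$end <- max(last$end, cur$end)
      keep_rows[[length(keep_rows)]] <- last
    } else {
      keep_rows[[length(keep_rows) + 1]] <- cur
    }
  }
  out <- do.call(rbind, keep_rows)
  rownames(out) <- NULL
  out
}

theta_from_segments <- function(seg_pair, L) {
  pop2_len <- 0
  for (s in seg_pair) {
    if (!is.null(s) && nrow(s) > 0) {
      pop2_len <- pop2_len + sum((s$end - s$start)[s$pop == 2L])
    }
  }
  pop2_len / (2 * L)
}

#' Forward-time admixture simulation with local-ancestry tracking
#'
#' Simulates a hybrid population founded by a 50-50 single-generation
#' admixture: every generation-1 individual has exactly one parent drawn
#' from each founder pool (so its ancestry proportion is exactly 0.5), and
#' each subsequent generation is produced by random mating within the
#' previous generation (two distinct parents per offspring, no selfing, no
#' enforced monogamy). Meiosis places `Poisson(L * recomb_rate)` crossovers
#' uniformly on the region; ancestry segments (0-based, half-open bp
#' intervals) are propagated through every meiosis and each individual's
#' true ancestry proportion `theta` is the fraction of its total haplotype
#' length inherited from population 2. Founder genotypes are split into two
#' haplotypes with heterozygote phase randomized.
#'
#' @param founders1,founders2 Unmixed founder genotypes for populations 1
#'   and 2: [genotype_table()]s (or matrices) over the same loci. No
#'   missing genotypes allowed.
#' @param n_offspring Diploid individuals per generation.
#' @param n_generations Total generations simulated, counting the admixture
#'   generation as generation 1 (so the value `7` reproduces one admixture
#'   generation plus six generations of random mating).
#' @param region_length_bp Length of the simulated region in bp; loci are
#'   evenly spaced over it.
#' @param recomb_rate Crossover rate per bp per generation.
#' @param mutation_rate Per-locus flip probability per transmission
#'   (default 0; at array-like scales mutation is negligible over a handful
#'   of generations).
#' @param seed Optional integer seed.
#' @return A [cohort()] of `n_offspring` admixed individuals (group 3) with
#'   tracked ancestry segments and exact `true_theta`.
#' @export
simulate_admixture <- function(founders1, founders2, n_offspring = 800,
                               n_generations = 7,
                               region_length_bp = 1.02e8,
                               recomb_rate = 1e-8, mutation_rate = 0,
                               seed = NULL) {
  g1 <- as_genotype_matrix(founders1)
  g2 <- as_genotype_matrix(founders2)
  if (ncol(g1) != ncol(g2)) stop("founder pools must share the same loci")
  if (nrow(g1) == 0 || nrow(g2) == 0) stop("empty founder pool")
  if (any(g1 == 9L) || any(g2 == 9L)) {
    stop("founder genotypes must be complete (no missing)")
  }
  if (n_generations < 1) stop("n_generations must be >= 1")
  local_rng(seed)
  m <- ncol(g1)
  L <- region_length_bp
  pos <- locus_positions(m, L)
  full_seg <- function(pop) {
    data.frame(start = 0, end = L, pop = as.integer(pop))
  }
  pool <- function(g, pop) {
    h <- split_haplotypes(g)
    lapply(seq_len(nrow(g)), function(i) list(
      haps = list(h$h1[i, ], h$h2[i, ]),
      segs = list(full_seg(pop), full_seg(pop))
    ))
  }
  pool1 <- pool(g1, 1L)
  pool2 <- pool(g2, 2L)

  breed <- function(parentA, parentB) {
    gamA <- make_gamete(parentA$haps[[1]], parentA$haps[[2]],
                        parentA$segs[[1]], parentA$segs[[2]],
                        pos, L, recomb_rate, mutation_rate)
    gamB <- make_gamete(parentB$haps[[1]], parentB$haps[[2]],
                        parentB$segs[[1]], parentB$segs[[2]],
                        pos, L, recomb_rate, mutation_rate)
    list(haps = list(gamA$allele, gamB$allele),
         segs = list(gamA$seg, gamB$seg))
  }

  # generation 1: one parent from each founder population
  gen <- lapply(seq_len(n_offspring), function(i) {
    breed(pool1[[sample.int(length(pool1), 1)]],
          pool2[[sample.int(length(pool2), 1)]])
  })
  # generations 2..n: random mating, two distinct parents
  if (n_generations >= 2) {
    for (t in 2:n_generations) {
      if (length(gen) < 2) stop("need at least 2 individuals to mate")
      gen <- lapply(seq_len(n_offspring), function(i) {
        pr <- sample.int(length(gen), 2, replace = FALSE)
        breed(gen[[pr[1]]], gen[[pr[2]]])
      })
    }
  }

  gmat <- t(vapply(gen, function(ind) ind$haps[[1]] + ind$haps[[2]],
                   integer(m)))
  if (m == 1) gmat <- matrix(gmat, ncol = 1)
  ids <- paste0("adm", seq_len(n_offspring))
  theta <- vapply(gen, function(ind) theta_from_segments(ind$segs, L),
                  numeric(1))
  gt <- genotype_table(gmat, ids)
  lb <- label_table(ids, rep(3L, n_offspring), theta)
  cohort(gt, lb, segments = lapply(gen, `[[`, "segs"))
}

#' Expand a pool of individuals by cyclic duplication
#'
#' Reaches exactly `target_count` individuals by copying individual
#' `i mod n` of the input into slot `i` of the output (so expanding 38
#' individuals to 100 triplicates the first 24 and duplicates the rest).
#' Labels, theta, segments and provenance are copied; duplicated rows get
#' distinct ids.
#'
#' @param cohort A non-empty [cohort()].
#' @param target_count Output size, `>=` the current size.
#' @return A `cohort` of `target_count` individuals.
#' @export
expand_pool <- function(cohort, target_count) {
  stopifnot(inherits(cohort, "cohort"))
  n <- n_individuals(cohort)
  if (n == 0) stop("empty cohort")
  if (target_count < n) stop("target_count must be >= current size")
  idx <- ((seq_len(target_count) - 1L) %% n) + 1L
  subset_cohort(cohort, idx)
}

#' Assemble the three-group study population
#'
#' Builds the full population the sampling-bias experiments draw from:
#' a forward-simulated admixed group plus two unmixed proxy groups expanded
#' by duplication, mirroring a design with 100 unmixed individuals per
#' ancestral population (expanded from 38 and 50 founders) and 800 admixed
#' individuals six generations after a 50-50 admixture.
#'
#' @param freqs A [gen_founder_frequencies()] result.
#' @param config An `experiment_config` (see [default_config()]); only the
#'   `population` section is used.
#' @param seed Optional integer seed.
#' @return A [cohort()] ordered as: unmixed population 1 (group 1,
#'   theta 0), unmixed population 2 (group 2, theta 1), admixed (group 3).
#' @export
assemble_study_population <- function(freqs, config = default_config(),
                                      seed = NULL) {
  stopifnot(inherits(freqs, "founder_freqs"))
  p <- config$population
  seeds <- derive_seeds(seed, 4)
  parts <- list()

  unmixed <- sample_founder_genotypes(freqs, p$n_unmixed_founders, seeds[1])
  u <- unmixed$labels$group
  parts$pop1 <- expand_pool(subset_cohort(unmixed, which(u == 1L)),
                            p$n_unmixed[1])
  parts$pop2 <- expand_pool(subset_cohort(unmixed, which(u == 2L)),
                            p$n_unmixed[2])

  if (p$n_admixed > 0) {
    adm_founders <- sample_founder_genotypes(freqs, p$n_admix_founders,
                                             seeds[2])
    ua <- adm_founders$labels$group
    parts$admixed <- simulate_admixture(
      subset_cohort(adm_founders, which(ua == 1L))$genotypes,
      subset_cohort(adm_founders, which(ua == 2L))$genotypes,
      n_offspring = p$n_admixed,
      n_generations = p$n_generations + 1L,  # admixture gen + random mating
      region_length_bp = p$region_length_bp,
      recomb_rate = p$recomb_rate,
      mutation_rate = p$mutation_rate,
      seed = seeds[3]
    )
  }
  do.call(bind_cohorts, unname(parts))
}
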