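#' Collapse duplicated individuals into weights
#'
#' Sampling with replacement and duplication-based pool expansion produce
#' cohorts with repeated rows. Because an integer likelihood weight is
#' algebraically identical to row duplication, repeated rows (same
#' provenance id) can be collapsed to one row with a count weight before
#' fitting, and the fitted `Q` rows expanded back afterwards. This is the
#' weighted-likelihood identity the correction machinery relies on, reused
#' as a computational device.
#'
#' @param x A [cohort()].
#' @return List with `cohort` (unique rows), `counts` (integer weights) and
#'   `expand` (index such that `unique[expand] == original`).
#' @export
collapse_duplicates <- function(x) {
  stopifnot(inherits(x, "cohort"))
  first <- !duplicated(x$provenance)
  uniq_idx <- which(first)
  expand <- match(x$provenance, x$provenance[uniq_idx])
  counts <- as.integer(tabulate(expand, nbins = length(uniq_idx)))
  list(cohort = subset_cohort(x, uniq_idx), counts = counts, expand = expand)
}

# Fit the configured engine on a (possibly duplicated) cohort and return the
# inferred per-row ancestry proxy, aligned to true theta. Duplicates are
# collapsed to integer weights for the EM engine; extra_weights (per row of
# the original sample) fold in the weighted-likelihood correction.
infer_ancestry_vector <- function(sample, inference, seed,
                                  extra_weights = NULL) {
  if (inference$engine == "em") {
    col <- collapse_duplicates(sample)
    w <- col$counts
    if (!is.null(extra_weights)) {
      # weights are group-constant, so constant within a provenance class
      w <- w * extra_weights[match(seq_along(col$counts), col$expand)]
    }
    fit <- admixture_em(
      col$cohort, K = inference$K, weights = w / mean(w),
      tol = inference$tol, max_iter = inference$max_iter,
      seed = seed, accelerate = isTRUE(inference$accelerate)
    )
    inferred <- fit$Q[col$expand, 1]
  } else {
    w <- if (is.null(extra_weights)) rep(1, n_individuals(sample))
         else extra_weights
    fit <- eigen_ancestry(sample, n_components = 1, weights = w)
    inferred <- fit$projections[, 1]
  }
  inferred
}

new_result_table <- function(rows) {
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (all(is.na(res$r2))) {
    agg <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      correction = character(0), mean = numeric(0),
                      se = numeric(0), n = numeric(0), tau = numeric(0))
  } else {
    agg <- stats::aggregate(
      r2 ~ x + y + z + correction,
      data = res,
      FUN = function(v) c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)),
                          n = length(v))
    )
    agg <- cbind(agg[c("x", "y", "z", "correction")],
                 as.data.frame(agg$r2))
    agg$tau <- ifelse(agg$x > 0, agg$y / agg$x, NA_real_)
  }
  structure(list(results = res, aggregate = agg), class = "result_table")
}

#' @export
print.result_table <- function(x, ...) {
  cat(sprintf("result_table: %d runs over %d cells\n",
              nrow(x$results), nrow(x$aggregate)))
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}

#' Sweep sampling designs over a study population
#'
#' The core biased-sampling experiment: for every grid cell `(x, y, z)` and
#' replicate, draw a biased dataset with replacement from the study
#' population, optionally apply a selection-bias correction (`resample` or
#' `weights`, with the configured group prior), infer ancestry with the
#' configured engine, and score the squared correlation against the true
#' ancestry of the analyzed rows. Results are aggregated to mean and
#' standard error per cell.
#'
#' @param config An `experiment_config` (see [default_config()] /
#'   [load_config()]).
#' @param population Optional pre-built study [cohort()]; built from
#'   `config` when omitted.
#' @param seed Integer seed governing population construction (when needed)
#'   and all sampling; defaults to `config$seed`.
#' @return A `result_table`: `$results` has one row per cell x replicate,
#'   `$aggregate` mean/SE per cell.
#' @export
run_grid_experiment <- function(config = default_config(),
                                population = NULL, seed = config$seed) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- derive_seeds(seed, 2)
  if (is.null(population)) {
    freqs <- gen_founder_frequencies(config$population$n_loci,
                                     config$population$fst, seeds[1])
    population <- assemble_study_population(freqs, config, seeds[1])
  }
  cells <- grid_cells(config)
  reps <- config$grid$replicates
  mode <- config$correction$mode
  prior <- config$correction$prior
  if (identical(prior, "uniform")) prior <- rep(1, 3) / 3
  cell_seeds <- matrix(derive_seeds(seeds[2], length(cells) * reps * 3),
                       ncol = 3)
  rows <- list()
  run <- 0L
  for (ci in seq_along(cells)) {
    spec <- cells[[ci]]
    for (r in seq_len(reps)) {
      run <- run + 1L
      s <- cell_seeds[run, ]
      out <- run_one_cell(population, spec, mode, prior,
                          config$inference, s)
      rows[[run]] <- data.frame(
        x = spec$x, y = spec$y, z = spec$z,
        tau = if (spec$x > 0) spec$y / spec$x else NA_real_,
        replicate = r, seed = s[1],
        engine = config$inference$engine, correction = mode,
        r2 = out$r2, error = out$error,
        stringsAsFactors = FALSE
      )
    }
  }
  new_result_table(rows)
}

# One biased draw + optional correction + inference + evaluation.
# seeds: (draw, correction, inference-init).
run_one_cell <- function(population, spec, mode, prior, inference, seeds) {
  r2 <- NA_real_
  err <- NA_character_
  res <- try({
    sample <- draw_biased_sample(population, spec, seeds[1])
    if (mode == "resample") {
      model <- selection_probabilities(spec, prior)
      analyzed <- resample_corrected(sample, model, seeds[2])
      inferred <- infer_ancestry_vector(analyzed, inference, seeds[3])
    } else if (mode == "weights") {
      model <- selection_probabilities(spec, prior)
      analyzed <- sample
      inferred <- infer_ancestry_vector(analyzed, inference, seeds[3],
                                        extra_weights =
                                          likelihood_weights(sample, model))
    } else {
      analyzed <- sample
      inferred <- infer_ancestry_vector(analyzed, inference, seeds[3])
    }
    squared_correlation(analyzed$labels$true_theta, inferred)
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    err <- conditionMessage(attr(res, "condition"))
  } else {
    r2 <- res
  }
  list(r2 = r2, error = err)
}

#' Scan the admixed-to-unmixed ratio for the accuracy threshold
#'
#' Sweeps `tau = y / x` at fixed symmetric unmixed counts (`x = z`),
#' running the uncorrected experiment at `y = tau * x`, and estimates the
#' largest ratio at which mean accuracy stays at or above the cutoff.
#'
#' @param config An `experiment_config`; its grid section is overridden.
#' @param population Optional pre-built study cohort.
#' @param taus Ratios to scan (default 1..10).
#' @param x Unmixed count per ancestral population (default 30).
#' @param seed Integer seed.
#' @return A `result_table` with an extra attribute `tau_threshold`.
#' @export
run_tau_scan <- function(config = default_config(), population = NULL,
                         taus = 1:10, x = 30, seed = config$seed) {
  cfg <- config
  cfg$grid$x <- as.integer(x)
  cfg$grid$y <- as.integer(taus * x)
  cfg$grid$z <- NULL
  cfg$correction$mode <- "none"
  tab <- run_grid_experiment(cfg, population, seed)
  attr(tab, "tau_threshold") <- estimate_tau_threshold(tab)
  tab
}

#' Largest scanned ratio with mean accuracy at or above a cutoff
#'
#' @param tab A `result_table` from [run_tau_scan()] or
#'   [run_grid_experiment()] over symmetric cells.
#' @param cutoff Mean squared-correlation cutoff (default 0.95).
#' @return The largest `tau` whose cell mean `r2 >= cutoff` (0 if none).
#' @export
estimate_tau_threshold <- function(tab, cutoff = 0.95) {
  stopifnot(inherits(tab, "result_table"))
  agg <- tab$aggregate
  ok <- agg$tau[is.finite(agg$tau) & agg$mean >= cutoff]
  if (length(ok) == 0) 0 else max(ok)
}

#' Paired comparison of corrected and uncorrected inference
#'
#' For every grid cell and replicate, the corrected and uncorrected arms
#' consume the *same* biased sample (paired seeds), so the per-dataset
#' accuracy change `delta = r2_corrected - r2_uncorrected` isolates the
#' effect of the correction.
#'
#' @inheritParams run_grid_experiment
#' @param mode Correction arm to compare against none: `"resample"`
#'   (default) or `"weights"`.
#' @return A data frame with per-dataset `r2_uncorrected`, `r2_corrected`,
#'   `delta`, plus an `aggregate` attribute of per-cell means.
#' @export
run_correction_comparison <- function(config = default_config(),
                                      population = NULL,
                                      mode = c("resample", "weights"),
                                      seed = config$seed) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "experiment_config"))
  seeds <- derive_seeds(seed, 2)
  if (is.null(population)) {
    freqs <- gen_founder_frequencies(config$population$n_loci,
                                     config$population$fst, seeds[1])
    population <- assemble_study_population(freqs, config, seeds[1])
  }
  prior <- config$correction$prior
  if (identical(prior, "uniform")) prior <- rep(1, 3) / 3
  cells <- grid_cells(config)
  reps <- config$grid$replicates
  cell_seeds <- matrix(derive_seeds(seeds[2], length(cells) * reps * 3),
                       ncol = 3)
  rows <- list()
  run <- 0L
  for (spec in cells) {
    for (r in seq_len(reps)) {
      run <- run + 1L
      s <- cell_seeds[run, ]
      un <- run_one_cell(population, spec, "none", prior,
                         config$inference, s)
      co <- run_one_cell(population, spec, mode, prior,
                         config$inference, s)
      rows[[run]] <- data.frame(
        x = spec$x, y = spec$y, z = spec$z, replicate = r, seed = s[1],
        r2_uncorrected = un$r2, r2_corrected = co$r2,
        delta = co$r2 - un$r2, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(r2_uncorrected, r2_corrected, delta) ~
                            x + y + z, data = res, FUN = mean)
  attr(res, "aggregate") <- agg
  res
}

#' Effective-population-size (bottleneck) experiment
#'
#' Reproduces the unequal-drift design: two populations split from a common
#' ancestor, population 2 passing through a bottleneck of strength `alpha`
#' (epochs 795/200/5 generations at sizes `n0, alpha*n0, n0`), population 1
#' at constant size. Differentiation is induced by mapping each demography
#' to its accumulated drift ([demography_to_drift()]) and drawing
#' Balding-Nichols founders with those per-population coefficients. A 50-50
#' pooled admixture plus five generations of random mating forms the
#' admixed group; the analyzed dataset contains all population-1 and
#' admixed individuals and a swept number `x` of population-2 individuals.
#' Optionally an effective-size-informed resampling correction is applied,
#' with group prior proportional to `(n0, Ne_2, n0)` — the admixed group is
#' assigned the effective size of population 1.
#'
#' @param config An `experiment_config`; uses its `demography`,
#'   `population$n_loci` and `inference` sections.
#' @param correct Also run the Ne-informed corrected arm (paired samples).
#' @param replicates Independent datasets per `alpha` (default
#'   `config$grid$replicates`).
#' @param seed Integer seed.
#' @return A data frame with columns `alpha, x, replicate, r2` (and
#'   `r2_corrected, delta` when `correct = TRUE`).
#' @export
run_bottleneck_experiment <- function(config = default_config(),
                                      correct = FALSE,
                                      replicates = config$grid$replicates,
                                      seed = config$seed) {
  stopifnot(inherits(config, "experiment_config"))
  d <- config$demography
  inf <- config$inference
  n_loci <- config$population$n_loci
  rows <- list()
  master <- derive_seeds(seed, length(d$alpha) * replicates)
  run <- 0L
  for (ai in seq_along(d$alpha)) {
    alpha <- d$alpha[ai]
    dem1 <- demography(d$split_generations, d$n0)
    dem2 <- bottleneck_scenario(alpha, d$n0)
    f1 <- demography_to_drift(dem1)
    f2 <- demography_to_drift(dem2)
    ne2 <- harmonic_mean_ne(dem2)
    prior <- c(d$n0, ne2, d$n0)
    prior <- prior / sum(prior)
    for (r in seq_len(replicates)) {
      run <- run + 1L
      s <- derive_seeds(master[run], 6)
      freqs <- gen_founder_frequencies(n_loci, drift_f = c(f1, f2),
                                       seed = s[1])
      founders <- sample_founder_genotypes(freqs, d$n_sampled, s[2])
      u <- founders$labels$group
      admixed <- simulate_admixture(
        subset_cohort(founders, which(u == 1L))$genotypes,
        subset_cohort(founders, which(u == 2L))$genotypes,
        n_offspring = d$n_admixed,
        n_generations = d$n_generations + 1L,
        region_length_bp = config$population$region_length_bp,
        recomb_rate = config$population$recomb_rate,
        seed = s[3]
      )
      study <- bind_cohorts(founders, admixed)
      grp <- study$labels$group
      pool2 <- which(grp == 2L)
      x_seeds <- derive_seeds(s[4], length(d$x_sweep))
      for (xi in seq_along(d$x_sweep)) {
        xv <- d$x_sweep[xi]
        xs <- derive_seeds(x_seeds[xi], 4)
        local_rng(xs[1])
        idx <- c(which(grp == 1L), which(grp == 3L),
                 sample(pool2, min(xv, length(pool2))))
        dataset <- subset_cohort(study, idx)
        r2 <- tryCatch(
          squared_correlation(
            dataset$labels$true_theta,
            infer_ancestry_vector(dataset, inf, xs[2])
          ),
          error = function(e) NA_real_
        )
        row <- data.frame(alpha = alpha, x = xv, replicate = r,
                          r2 = r2, stringsAsFactors = FALSE)
        if (correct) {
          spec <- sample_spec(sum(grp == 1L), sum(grp == 3L),
                              min(xv, length(pool2)))
          model <- selection_probabilities(spec, prior)
          corrected <- resample_corrected(dataset, model, xs[3])
          row$r2_corrected <- tryCatch(
            squared_correlation(
              corrected$labels$true_theta,
              infer_ancestry_vector(corrected, inf, xs[4])
            ),
            error = function(e) NA_real_
          )
          row$delta <- row$r2_corrected - row$r2
        }
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
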