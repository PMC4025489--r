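#' Sampling design for a biased dataset
#'
#' A design `(x, y, z)` counts how many unmixed population-1 individuals
#' (`x`), admixed individuals (`y`) and unmixed population-2 individuals
#' (`z`) are drawn, with replacement, into the analyzed dataset.
#'
#' @param x,y,z Non-negative integer counts (at least one positive).
#' @return An object of class `sample_spec`.
#' @examples
#' sample_spec(10, 700, 10)
#' @export
sample_spec <- function(x, y, z) {
  counts <- c(x = x, y = y, z = z)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != floor(counts))) {
    stop("x, y, z must be non-negative integers")
  }
  if (sum(counts) == 0) stop("at least one of x, y, z must be positive")
  structure(list(x = as.integer(x), y = as.integer(y), z = as.integer(z)),
            class = "sample_spec")
}

#' @export
print.sample_spec <- function(x, ...) {
  cat(sprintf("S_{%d,%d,%d} (n = %d%s)\n", x$x, x$y, x$z,
              x$x + x$y + x$z,
              if (x$x == x$z && x$x > 0)
                sprintf(", tau = %.3g", x$y / x$x) else ""))
  invisible(x)
}

#' Group-level selection model
#'
#' For selection that depends on the data only through the group label `u`,
#' the inclusion probability of a group is proportional to its sample count
#' divided by its population prior: `P(s=1|u) = P(u|s=1) P(s=1) / P(u)`,
#' and with sample counts `(x, y, z)` and a uniform prior this reduces to
#' `P(s=1|u=1) : P(s=1|u=2) : P(s=1|u=3) = x : z : y` up to a constant that
#' never needs evaluating. The correction factor of a group is the
#' reciprocal selection weight times the prior, again up to a constant.
#'
#' @param spec A [sample_spec()] (counts of groups 1, 3, 2 as `x, y, z`).
#' @param group_prior Population prior `P(u)` over groups `(1, 2, 3)`;
#'   default uniform. Must sum to 1.
#' @return An object of class `selection_model` with components
#'   `group_prior`, `selection_weight` and `correction_factor`, each a
#'   length-3 vector indexed by group.
#' @examples
#' selection_probabilities(sample_spec(10, 700, 10))
#' @export
selection_probabilities <- function(spec, group_prior = rep(1, 3) / 3) {
  stopifnot(inherits(spec, "sample_spec"))
  if (length(group_prior) != 3 || any(group_prior < 0)) {
    stop("group_prior must be 3 non-negative values")
  }
  if (abs(sum(group_prior) - 1) > 1e-8) stop("group_prior must sum to 1")
  counts <- c(spec$x, spec$z, spec$y)  # indexed by group u = 1, 2, 3
  undefined <- group_prior > 0 & counts == 0
  if (any(undefined)) {
    stop("correction undefined: group(s) ",
         paste(which(undefined), collapse = ", "),
         " have positive prior but zero sample count")
  }
  weight <- ifelse(group_prior > 0, counts / group_prior, 0)
  corr <- ifelse(group_prior > 0, group_prior / counts, 0)
  structure(list(
    group_prior = group_prior,
    selection_weight = weight / sum(weight),
    correction_factor = corr / sum(corr)
  ), class = "selection_model")
}

#' @export
print.selection_model <- function(x, ...) {
  df <- data.frame(
    group = 1:3, prior = x$group_prior,
    selection_weight = x$selection_weight,
    correction_factor = x$correction_factor
  )
  cat("selection_model (weights and corrections up to a constant)\n")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Draw a biased dataset from a study population
#'
#' Samples, with replacement, `x` individuals from group 1, `y` from the
#' admixed group 3 and `z` from group 2, concatenated in that order.
#' Individuals drawn more than once appear as distinct rows; provenance ids
#' record the source individual.
#'
#' @param cohort A [cohort()] containing every group the spec requests.
#' @param spec A [sample_spec()].
#' @param seed Optional integer seed.
#' @return A `cohort` of `x + y + z` rows.
#' @export
draw_biased_sample <- function(cohort, spec, seed = NULL) {
  stopifnot(inherits(cohort, "cohort"), inherits(spec, "sample_spec"))
  local_rng(seed)
  u <- cohort$labels$group
  pick <- function(group, n) {
    pool <- which(u == group)
    if (n > 0 && length(pool) == 0) {
      stop("requested group ", group, " absent from cohort")
    }
    if (n == 0) integer(0) else sample(pool, n, replace = TRUE)
  }
  idx <- c(pick(1L, spec$x), pick(3L, spec$y), pick(2L, spec$z))
  subset_cohort(cohort, idx)
}

#' Resampling correction for a biased sample
#'
#' Implements the selection-bias correction by sampling the selected sample
#' with replacement, each point included with probability proportional to
#' its correction factor `1/P(s=1|u_i)` (normalized over the sample). The
#' output has the same size `N` as the input and may contain non-unique
#' points; in expectation its group composition matches the model's prior.
#'
#' @param sample A `cohort` (typically from [draw_biased_sample()]).
#' @param model A `selection_model` from [selection_probabilities()].
#' @param seed Optional integer seed.
#' @return A `cohort` of the same size, resampled toward the prior.
#' @export
resample_corrected <- function(sample, model, seed = NULL) {
  stopifnot(inherits(sample, "cohort"), inherits(model, "selection_model"))
  w <- model$correction_factor[sample$labels$group]
  if (all(w == 0)) stop("degenerate correction: all weights zero")
  if (any(!is.finite(w))) stop("non-finite correction factor")
  local_rng(seed)
  n <- n_individuals(sample)
  idx <- sample.int(n, n, replace = TRUE, prob = w / sum(w))
  subset_cohort(sample, idx)
}

#' Weighted-likelihood correction factors
#'
#' The correction implemented as per-individual likelihood weights instead
#' of resampling: each individual is weighted by its group's correction
#' factor `1/P(s=1|u)`, normalized to mean 1 so weighted log-likelihoods
#' remain comparable to unweighted ones. Equivalent to the resampling
#' correction in expected per-group mass, without the extra randomness.
#'
#' @param sample A `cohort`.
#' @param model A `selection_model`.
#' @return Numeric vector of positive weights with mean 1.
#' @export
likelihood_weights <- function(sample, model) {
  stopifnot(inherits(sample, "cohort"), inherits(model, "selection_model"))
  w <- model$correction_factor[sample$labels$group]
  if (any(!is.finite(w)) || all(w == 0)) stop("degenerate correction weights")
  w / mean(w)
}
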