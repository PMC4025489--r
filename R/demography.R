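#' Piecewise-constant demography
#'
#' A demography is an ordered sequence of epochs, each with a duration in
#' generations and a constant diploid population size. Epochs are listed from
#' past to present.
#'
#' @param durations Numeric vector of epoch durations in generations (> 0).
#' @param sizes Numeric vector of diploid population sizes (> 0), same length
#'   as `durations`.
#' @return An object of class `demography`: a data frame with columns
#'   `duration` and `size`.
#' @examples
#' demography(c(795, 200, 5), c(1e4, 1e3, 1e4))
#' @export
demography <- function(durations, sizes) {
  if (length(durations) != length(sizes) || length(durations) == 0) {
    stop("durations and sizes must be non-empty vectors of equal length")
  }
  if (any(!is.finite(durations)) || any(durations <= 0)) {
    stop("all epoch durations must be positive and finite")
  }
  if (any(!is.finite(sizes)) || any(sizes <= 0)) {
    stop("all population sizes must be positive and finite")
  }
  structure(
    data.frame(duration = as.numeric(durations), size = as.numeric(sizes)),
    class = c("demography", "data.frame")
  )
}

#' @export
print.demography <- function(x, ...) {
  cat(sprintf(
    "Piecewise-constant demography: %d epoch(s), %g generations total\n",
    nrow(x), sum(x$duration)
  ))
  print.data.frame(x, ...)
  invisible(x)
}

#' Bottleneck demography scenario
#'
#' Builds the three-epoch history used to study the impact of effective
#' population size on sampling bias: a population of size `n0` persists for
#' 795 generations after a split, contracts instantaneously to `alpha * n0`
#' for 200 generations, then recovers instantaneously to `n0` for the final
#' 5 generations before sampling.
#'
#' @param alpha Contraction factor in (0, 1]; `alpha = 1` gives a
#'   constant-size population.
#' @param n0 Baseline diploid population size.
#' @return A [demography()] with epochs `(795, n0), (200, alpha*n0), (5, n0)`.
#' @examples
#' bottleneck_scenario(0.1, 1e4)
#' @export
bottleneck_scenario <- function(alpha, n0 = 1e4) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha <= 0 || alpha > 1) {
    stop("alpha must be a single value in (0, 1]")
  }
  demography(c(795, 200, 5), c(n0, alpha * n0, n0))
}

#' Long-term effective population size (harmonic mean)
#'
#' Over a piecewise-constant demography the long-term effective size is the
#' harmonic mean of the per-generation sizes,
#' `Ne = T / sum_i(t_i / N_i)` with `T = sum_i t_i`. A 10-fold bottleneck for
#' 200 of 1000 generations reduces a population of 10^4 to about 0.36 of its
#' baseline size.
#'
#' @param dem A [demography()].
#' @return Effective diploid population size (scalar).
#' @examples
#' harmonic_mean_ne(bottleneck_scenario(0.1, 1e4)) / 1e4  # ~0.357
#' @export
harmonic_mean_ne <- function(dem) {
  stopifnot(inherits(dem, "demography"))
  sum(dem$duration) / sum(dem$duration / dem$size)
}

#' Map a demography onto a single drift coefficient
#'
#' Accumulated genetic drift over the demography, expressed as the
#' Balding-Nichols dispersion parameter `F = 1 - exp(-sum_i t_i / (2 N_i))`.
#' This lets a demographic history parameterize the founder-frequency
#' generator directly, so differentiation scenarios with unequal effective
#' sizes can be simulated without a coalescent engine.
#'
#' @param dem A [demography()].
#' @return Drift coefficient `F` in (0, 1).
#' @examples
#' demography_to_drift(demography(1000, 1e4))  # 1 - exp(-0.05)
#' @export
demography_to_drift <- function(dem) {
  stopifnot(inherits(dem, "demography"))
  1 - exp(-sum(dem$duration / (2 * dem$size)))
}
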