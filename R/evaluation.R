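#' Squared correlation between true and inferred ancestry
#'
#' The accuracy measure for ancestry recovery: the squared Pearson
#' correlation between the true ancestry proportions and the inferred ones.
#' With two ancestral components it is symmetric in the component used
#' (`cor(theta, Q1)^2 == cor(theta, Q2)^2` since `Q2 = 1 - Q1`), so label
#' switching does not affect it, nor does any affine rescaling of the
#' inferred axis (which is why eigenvector projections can be scored the
#' same way).
#'
#' @param true_theta Numeric vector of true ancestry proportions.
#' @param inferred Numeric vector of inferred ancestry (same length).
#' @return Squared correlation in `[0, 1]`.
#' @examples
#' squared_correlation(c(0, 0.5, 1), c(0.1, 0.4, 0.95))
#' @export
squared_correlation <- function(true_theta, inferred) {
  if (length(true_theta) != length(inferred)) {
    stop("true_theta and inferred must have equal length")
  }
  if (length(true_theta) < 3) stop("need at least 3 individuals")
  if (anyNA(true_theta) || anyNA(inferred)) stop("missing values not allowed")
  if (stats::sd(true_theta) == 0 || stats::sd(inferred) == 0) {
    stop("squared correlation undefined for a constant vector")
  }
  stats::cor(true_theta, inferred)^2
}

#' Ratio of admixed to unmixed individuals in a sampling design
#'
#' The bias summary statistic for a sampling design `(x, y, z)`: the number
#' of admixed individuals per unmixed individual from each ancestral
#' population, `y / x`. It is defined for symmetric designs (`x == z`); for
#' asymmetric designs `y / x` is still returned, with a warning.
#'
#' @param spec A [sample_spec()].
#' @return The ratio `y / x`.
#' @examples
#' tau_sample(sample_spec(10, 100, 10))  # 10
#' @export
tau_sample <- function(spec) {
  stopifnot(inherits(spec, "sample_spec"))
  if (spec$x == 0) stop("tau undefined for x = 0")
  if (spec$x != spec$z) {
    warning("tau is defined for symmetric designs (x == z); using y/x anyway")
  }
  spec$y / spec$x
}

#' Permutation test for the ancestry correlation
#'
#' Significance of the squared correlation between true and inferred
#' ancestry by random permutation of the inferred vector (a Mantel-style
#' test on the two ancestry vectors). The p-value uses the standard
#' add-one estimator `p = (1 + #{r2_perm >= r2_obs}) / (n_perm + 1)`, so
#' with 999 permutations a perfect correlation attains p = 10^-3.
#'
#' @param true_theta,inferred As in [squared_correlation()].
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional integer seed; the global RNG state is restored.
#' @return Permutation p-value in (0, 1].
#' @export
permutation_pvalue <- function(true_theta, inferred, n_perm = 999, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  r2_obs <- squared_correlation(true_theta, inferred)
  local_rng(seed)
  r2_perm <- vapply(seq_len(n_perm), function(b) {
    stats::cor(true_theta, sample(inferred))^2
  }, numeric(1))
  (1 + sum(r2_perm >= r2_obs)) / (n_perm + 1)
}

#' Hudson's F_ST estimator (ratio of averages)
#'
#' Differentiation between two population samples of biallelic genotypes,
#' using the Hudson estimator in ratio-of-averages form: the mean over loci
#' of the numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`
#' divided by the mean over loci of the denominator
#' `p1(1-p2) + p2(1-p1)`, where `p` are sample allele frequencies and `n`
#' allele counts are haploid sample sizes. Loci monomorphic in both samples
#' are dropped. The ratio-of-averages form is robust to rare alleles.
#'
#' @param genotypes_pop1,genotypes_pop2 Integer matrices (individuals x
#'   loci, values 0/1/2, 9 = missing) over the same loci, or
#'   `genotype_table` objects.
#' @return The F_ST estimate (can be slightly negative by sampling noise).
#' @export
hudson_fst <- function(genotypes_pop1, genotypes_pop2) {
  g1 <- as_genotype_matrix(genotypes_pop1)
  g2 <- as_genotype_matrix(genotypes_pop2)
  if (ncol(g1) != ncol(g2)) stop("populations must share the same loci")
  if (nrow(g1) < 2 || nrow(g2) < 2) {
    stop("need at least 2 individuals per population")
  }
  af <- function(g) {
    g[g == 9L] <- NA_integer_
    n <- 2 * colSums(!is.na(g))
    p <- colSums(g, na.rm = TRUE) / n
    list(p = p, n = n)
  }
  a1 <- af(g1); a2 <- af(g2)
  p1 <- a1$p; p2 <- a2$p; n1 <- a1$n; n2 <- a2$n
  keep <- is.finite(p1) & is.finite(p2) & n1 > 1 & n2 > 1 &
    !(pmin(p1, p2) == 0 & pmax(p1, p2) == 0) &
    !(pmin(p1, p2) == 1 & pmax(p1, p2) == 1)
  if (!any(keep)) stop("all loci monomorphic in both populations")
  p1 <- p1[keep]; p2 <- p2[keep]; n1 <- n1[keep]; n2 <- n2[keep]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  mean(num) / mean(den)
}
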