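#' Admixture-model ancestry inference by EM
#'
#' Maximum-likelihood estimation of individual ancestry proportions `Q`
#' (N x K, rows on the probability simplex) and ancestral allele
#' frequencies `P` (K x M) under the standard admixture likelihood for
#' unlinked biallelic genotypes,
#' \deqn{\ell = \sum_i w_i \sum_j [ g_{ij} \log \pi_{ij} +
#'   (2 - g_{ij}) \log(1 - \pi_{ij}) ], \quad
#'   \pi_{ij} = \sum_k q_{ik} p_{kj},}
#' fitted by expectation-maximization. The log-likelihood is non-decreasing
#' across iterations (asserted on every run). Three variants share the one
#' engine:
#'
#' * **weighted**: per-individual weights `w` multiply likelihood
#'   contributions, so an integer weight is algebraically identical to
#'   duplicating the row; used for the weighted-likelihood bias correction.
#' * **semi-supervised**: `fixed_labels` pins individuals of known ancestry
#'   to a single component; their `q` rows stay at the vertex but they
#'   still inform the allele-frequency updates.
#' * **accelerated**: an optional extrapolated (SQUAREM-type) step with a
#'   fallback to the plain EM step whenever extrapolation would decrease
#'   the likelihood, preserving monotonicity.
#'
#' Missing genotypes (code 9) are excluded from all sums. Frequencies are
#' clamped to `[eps, 1 - eps]`. `Q` is initialized from a symmetric
#' Dirichlet(1); `P` from the sample allele frequency jittered per
#' component (a single start; run with different seeds to probe
#' multimodality).
#'
#' @param genotypes A [genotype_table()], [cohort()] or integer matrix
#'   (individuals x loci, 0/1/2, 9 missing).
#' @param K Number of ancestral components (>= 1, <= N).
#' @param weights Optional positive per-individual weights, conventionally
#'   mean 1 (default all 1).
#' @param fixed_labels Optional integer vector: `NA` (or 0) = unsupervised,
#'   `k` pins the individual to component `k`.
#' @param tol Convergence threshold on the log-likelihood increase.
#' @param max_iter Maximum EM sweeps.
#' @param seed Optional integer seed for the initialization.
#' @param accelerate Use the safeguarded extrapolated steps (default FALSE).
#' @param eps Allele-frequency clamp, default `1e-6`.
#' @param init Optional explicit start: a list with `Q` (N x K) and `P`
#'   (K x M), overriding the seeded random initialization.
#' @return An object of class `admixture_fit`: list with `Q`, `P`,
#'   `loglik`, `loglik_trace`, `n_iter`, `converged`, `K`, `weights`.
#' @export
admixture_em <- function(genotypes, K = 2, weights = NULL,
                         fixed_labels = NULL, tol = 1e-4, max_iter = 2000,
                         seed = NULL, accelerate = FALSE, eps = 1e-6,
                         init = NULL) {
  G <- as_genotype_matrix(genotypes)
  n <- nrow(G); m <- ncol(G)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K cannot exceed the number of individuals")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be positive, one per individual")
  }
  pinned <- integer(n)
  if (!is.null(fixed_labels)) {
    if (length(fixed_labels) != n) stop("fixed_labels must match individuals")
    fl <- as.integer(fixed_labels)
    fl[is.na(fl)] <- 0L
    if (any(fl < 0 | fl > K)) stop("fixed_labels must be NA or in 1..K")
    pinned <- fl
  }

  if (is.null(init)) {
    local_rng(seed)
    # Dirichlet(1) rows for Q; pinned rows start (and stay) at their vertex
    q0 <- matrix(stats::rgamma(n * K, 1), n, K)
    q0 <- q0 / rowSums(q0)
    for (i in which(pinned > 0)) {
      q0[i, ] <- 0
      q0[i, pinned[i]] <- 1
    }
    # frequency-anchored init for P
    Gna <- G
    Gna[Gna == 9L] <- NA_integer_
    phat <- colSums(Gna * weights, na.rm = TRUE) /
      (2 * colSums((!is.na(Gna)) * weights))
    phat[!is.finite(phat)] <- 0.5
    p0 <- t(vapply(seq_len(K), function(k) {
      pmin(pmax(phat + stats::runif(m, -0.1, 0.1), eps), 1 - eps)
    }, numeric(m)))
    if (m == 1) p0 <- matrix(p0, nrow = K)
  } else {
    q0 <- as.matrix(init$Q)
    p0 <- as.matrix(init$P)
    if (nrow(q0) != n || ncol(q0) != K) stop("init$Q has wrong dimensions")
    if (nrow(p0) != K || ncol(p0) != m) stop("init$P has wrong dimensions")
  }

  res <- admix_em_cpp(G, q0, p0, as.numeric(weights), pinned,
                      tol, as.integer(max_iter), eps, accelerate)
  trace <- res$loglik_trace
  if (any(diff(trace) < -1e-6 * pmax(1, abs(trace[-1])))) {
    stop("internal error: log-likelihood decreased during EM")
  }
  Q <- res$Q; P <- res$P
  rownames(Q) <- rownames(G)
  colnames(P) <- colnames(G)
  structure(list(
    Q = Q, P = P,
    loglik = trace[length(trace)], loglik_trace = trace,
    n_iter = res$n_iter, converged = res$converged,
    K = K, weights = weights
  ), class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf(
    "admixture_fit: K = %d, %d individuals, loglik = %.2f (%s, %d sweeps)\n",
    x$K, nrow(x$Q), x$loglik,
    if (x$converged) "converged" else "max_iter reached", x$n_iter
  ))
  invisible(x)
}

#' Admixture-model log-likelihood
#'
#' The weighted binomial log-likelihood the EM engine maximizes, evaluated
#' at given parameters. Missing genotypes contribute nothing; an
#' all-missing dataset scores 0; scaling all weights by a constant scales
#' the value by the same constant.
#'
#' @inheritParams admixture_em
#' @param Q N x K ancestry matrix, rows on the simplex.
#' @param P K x M allele-frequency matrix.
#' @param eps Clamp applied to `pi` before taking logs.
#' @return The log-likelihood (scalar).
#' @export
loglikelihood <- function(genotypes, Q, P, weights = NULL, eps = 1e-6) {
  G <- as_genotype_matrix(genotypes)
  Q <- as.matrix(Q); P <- as.matrix(P)
  if (nrow(Q) != nrow(G)) stop("Q rows must match individuals")
  if (ncol(P) != ncol(G)) stop("P columns must match loci")
  if (ncol(Q) != nrow(P)) stop("Q and P disagree on K")
  if (is.null(weights)) weights <- rep(1, nrow(G))
  admix_loglik_cpp(G, Q, P, as.numeric(weights), eps)
}

#' Ancestry inference by standardized eigenanalysis
#'
#' PCA of the standardized genotype matrix: each locus is centered at twice
#' its sample allele frequency and scaled by the binomial standard
#' deviation `sqrt(phat (1 - phat))`; missing genotypes are mean-imputed;
#' individuals are projected on the top eigenvectors of the resulting
#' covariance. In a two-population admixture the first projection proxies
#' ancestry. With weights, allele frequencies and the decomposed covariance
#' are weight-adjusted so that an integer-weighted fit matches the
#' row-duplicated unweighted fit.
#'
#' @inheritParams admixture_em
#' @param n_components Number of leading projections to return.
#' @return An object of class `eigen_fit`: `eigenvalues` (descending, all
#'   of them) and `projections` (N x `n_components`).
#' @export
eigen_ancestry <- function(genotypes, n_components = 1, weights = NULL) {
  G <- as_genotype_matrix(genotypes)
  n <- nrow(G); m <- ncol(G)
  if (n < 2) stop("need at least 2 individuals")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0)) {
    stop("weights must be positive, one per individual")
  }
  X <- matrix(as.numeric(G), n, m)
  X[X == 9] <- NA_real_
  wsum <- colSums((!is.na(X)) * weights)
  phat <- colSums(X * weights, na.rm = TRUE) / (2 * wsum)
  poly <- is.finite(phat) & phat > 0 & phat < 1
  X <- X[, poly, drop = FALSE]
  phat <- phat[poly]
  X <- sweep(X, 2, 2 * phat)
  X[is.na(X)] <- 0  # mean imputation after centering
  # a locus with no genotype variance is monomorphic in the sample even if
  # its allele frequency is interior (e.g. all heterozygotes)
  varying <- colSums(X^2) > 0
  if (!any(varying)) stop("all loci monomorphic")
  X <- X[, varying, drop = FALSE]
  phat <- phat[varying]
  X <- sweep(X, 2, sqrt(phat * (1 - phat)), "/")
  Xw <- X * sqrt(weights)
  nc <- min(n_components, n - 1, ncol(X))
  sv <- svd(Xw, nu = 0, nv = nc)
  projections <- X %*% sv$v
  rownames(projections) <- rownames(G)
  structure(list(
    eigenvalues = sv$d^2 / ncol(X),
    projections = projections
  ), class = "eigen_fit")
}

#' @export
print.eigen_fit <- function(x, ...) {
  cat(sprintf(
    "eigen_fit: %d individuals, top eigenvalues: %s\n",
    nrow(x$projections),
    paste(sprintf("%.3f", utils::head(x$eigenvalues, 3)), collapse = ", ")
  ))
  invisible(x)
}

#' Resolve label switching against a reference
#'
#' Ancestry components are exchangeable, so fitted columns of `Q` are
#' permuted to make column 1 the one most correlated with the reference
#' (true ancestry proportions or pinned labels); `P` rows are permuted
#' accordingly. The squared-correlation accuracy measure is invariant to
#' this relabeling; alignment only fixes the orientation for reporting.
#'
#' @param fit An `admixture_fit`.
#' @param reference Numeric vector (length N) to align column 1 against.
#' @return The fit with columns of `Q` (and rows of `P`) permuted; the
#'   permutation used is stored as `$alignment`.
#' @export
align_clusters <- function(fit, reference) {
  stopifnot(inherits(fit, "admixture_fit"))
  if (length(reference) != nrow(fit$Q)) stop("reference length must match Q")
  K <- fit$K
  cors <- vapply(seq_len(K), function(k) {
    if (stats::sd(fit$Q[, k]) == 0) return(-Inf)
    stats::cor(fit$Q[, k], reference)
  }, numeric(1))
  best <- which.max(cors)
  perm <- c(best, setdiff(seq_len(K), best))
  fit$Q <- fit$Q[, perm, drop = FALSE]
  fit$P <- fit$P[perm, , drop = FALSE]
  fit$alignment <- perm
  fit
}
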