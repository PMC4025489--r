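test_that("K = 1 has the closed-form solution", {
  withr::with_seed(61, {
    g <- matrix(rbinom(8 * 40, 2, 0.3), 8, 40)
  })
  fit <- admixture_em(g, K = 1, seed = 1, tol = 1e-10, max_iter = 200)
  expect_true(all(fit$Q == 1))
  expect_equal(as.numeric(fit$P), colMeans(g) / 2, tolerance = 1e-6)
})

test_that("two-individual toy matches a brute-force grid maximization", {
  g <- rbind(c(0L, 0L), c(2L, 2L))
  fit <- admixture_em(g, K = 2, seed = 2, tol = 1e-12, max_iter = 5000)
  fit <- align_clusters(fit, c(0, 1))
  # Q converges to the identity configuration (after alignment, column 1
  # tracks the second individual's component)
  expect_equal(unname(fit$Q), rbind(c(0, 1), c(1, 0)), tolerance = 1e-3)
  # P rows approach the frequency clamp bounds
  expect_true(all(abs(fit$P[fit$P > 0.5] - 1) < 1e-3))
  expect_true(all(abs(fit$P[fit$P < 0.5]) < 1e-3))

  # independent coarse-to-fine grid oracle over (q1, q2, p1, p2) with
  # locus-symmetric parameters (both loci share one frequency per component)
  ll_toy <- function(q1, q2, p1, p2) {
    pi1 <- q1 * p1 + (1 - q1) * p2
    pi2 <- q2 * p1 + (1 - q2) * p2
    2 * (2 * log(1 - pi1)) + 2 * (2 * log(pi2))
  }
  grid_max <- function(qs, ps) {
    best <- -Inf
    for (q1 in qs) for (q2 in qs) {
      v <- outer(ps, ps, function(a, b) ll_toy(q1, q2, a, b))
      best <- max(best, max(v))
    }
    best
  }
  coarse <- grid_max(seq(0, 1, by = 0.05), seq(0.001, 0.999, by = 0.02))
  fine <- grid_max(c(0, 1), seq(0.001, 0.999, by = 0.001))
  oracle <- max(coarse, fine)
  # EM attains at least the grid optimum (it can exceed it: the clamp bound
  # 1e-6 is finer than the grid step)
  expect_gte(fit$loglik, oracle - 1e-6)
  expect_lt(abs(fit$loglik - oracle), 0.05)
})

test_that("integer weights are equivalent to duplicated rows", {
  withr::with_seed(63, {
    g <- matrix(rbinom(5 * 30, 2, runif(30)), 5, 30, byrow = FALSE)
  })
  w <- c(1, 3, 2, 1, 2)
  reps <- rep(seq_len(5), w)
  gdup <- g[reps, ]
  q0 <- matrix(rep(c(0.6, 0.4), each = 5), 5, 2)
  p0 <- matrix(runif(2 * 30, 0.2, 0.8), 2, 30)

  for (accel in c(FALSE, TRUE)) {
    for (iters in c(1, 3, 10)) {
      fw <- admixture_em(g, K = 2, weights = w, init = list(Q = q0, P = p0),
                         tol = 1e-300, max_iter = iters, accelerate = accel)
      fd <- admixture_em(gdup, K = 2, init = list(Q = q0[reps, ], P = p0),
                         tol = 1e-300, max_iter = iters, accelerate = accel)
      # identical frequency trajectories and pooled likelihood
      expect_lt(max(abs(fw$P - fd$P)), 1e-10)
      expect_equal(fw$loglik, fd$loglik, tolerance = 1e-9)
      # duplicated copies carry the weighted run's Q rows
      expect_lt(max(abs(fw$Q[reps, ] - fd$Q)), 1e-10)
    }
  }
})

test_that("log-likelihood is monotone over random runs", {
  withr::with_seed(64, {
    for (rep in 1:8) {
      n <- sample(4:12, 1); m <- sample(10:60, 1)
      g <- matrix(rbinom(n * m, 2, runif(m)), n, m, byrow = TRUE)
      g[runif(n * m) < 0.05] <- 9L  # sprinkle missingness
      accel <- rep %% 2 == 0
      fit <- admixture_em(g, K = 2, seed = rep, tol = 1e-8, max_iter = 300,
                          accelerate = accel)
      expect_true(all(diff(fit$loglik_trace) >=
                        -1e-6 * pmax(1, abs(fit$loglik_trace[-1]))))
      expect_true(all(abs(rowSums(fit$Q) - 1) < 1e-8))
      expect_true(all(fit$P > 0 & fit$P < 1))
    }
  })
})

test_that("weighted run with unit weights equals the unweighted run", {
  withr::with_seed(65, {
    g <- matrix(rbinom(6 * 25, 2, 0.4), 6, 25)
  })
  f1 <- admixture_em(g, K = 2, seed = 9, tol = 1e-6, max_iter = 100)
  f2 <- admixture_em(g, K = 2, weights = rep(1, 6), seed = 9, tol = 1e-6,
                     max_iter = 100)
  expect_identical(f1$Q, f2$Q)
  expect_identical(f1$P, f2$P)
  expect_identical(f1$loglik_trace, f2$loglik_trace)
})

test_that("the likelihood evaluates hand-checked cases", {
  # one heterozygote at one locus with pi = 1/2: log(1/2) + log(1/2)
  expect_equal(loglikelihood(matrix(1L, 1, 1), matrix(1, 1, 1),
                             matrix(0.5, 1, 1)),
               2 * log(0.5), tolerance = 1e-12)
  # all-missing data contributes nothing
  expect_equal(loglikelihood(matrix(9L, 3, 4), matrix(1, 3, 1),
                             matrix(0.5, 1, 4)), 0)
  # weights scale the objective linearly
  withr::with_seed(66, {
    g <- matrix(rbinom(4 * 10, 2, 0.5), 4, 10)
    q <- matrix(rgamma(8, 1), 4, 2); q <- q / rowSums(q)
    p <- matrix(runif(20, 0.1, 0.9), 2, 10)
  })
  l1 <- loglikelihood(g, q, p)
  l3 <- loglikelihood(g, q, p, weights = rep(3, 4))
  expect_equal(l3, 3 * l1, tolerance = 1e-9)
})

test_that("semi-supervision pins ancestry rows but not frequencies", {
  pop <- tiny_population(n_loci = 150)
  s <- draw_biased_sample(pop, sample_spec(15, 30, 15), seed = 71)
  labels <- ifelse(s$labels$group == 1L, 2L,
                   ifelse(s$labels$group == 2L, 1L, NA_integer_))
  fit <- admixture_em(s, K = 2, fixed_labels = labels, seed = 3,
                      tol = 1e-3, max_iter = 300, accelerate = TRUE)
  pinned <- which(!is.na(labels))
  expect_true(all(fit$Q[pinned, ] %in% c(0, 1)))
  # pinned individuals still inform P: frequencies differ between components
  expect_gt(mean(abs(fit$P[1, ] - fit$P[2, ])), 0.05)
  r2 <- squared_correlation(s$labels$true_theta, fit$Q[, 1])
  expect_gt(r2, 0.8)
})

test_that("ancestry is recovered on a balanced draw from the tiny cohort", {
  pop <- tiny_population()
  s <- draw_biased_sample(pop, sample_spec(40, 40, 40), seed = 81)
  fit <- admixture_em(s, K = 2, seed = 4, tol = 1e-3, max_iter = 400,
                      accelerate = TRUE)
  expect_gt(squared_correlation(s$labels$true_theta, fit$Q[, 1]), 0.95)
})

test_that("eigen-ancestry separates clusters and matches the SVD oracle", {
  # two point-clusters project apart with zero within-cluster spread
  g <- rbind(matrix(0L, 4, 12), matrix(2L, 4, 12))
  ef <- eigen_ancestry(g, n_components = 1)
  expect_equal(sd(ef$projections[1:4, 1]), 0, tolerance = 1e-9)
  expect_equal(sd(ef$projections[5:8, 1]), 0, tolerance = 1e-9)
  expect_gt(abs(mean(ef$projections[1:4, 1]) - mean(ef$projections[5:8, 1])),
            1)

  withr::with_seed(67, {
    g <- matrix(rbinom(20 * 50, 2, runif(50, 0.2, 0.8)), 20, 50, byrow = TRUE)
  })
  ef <- eigen_ancestry(g, n_components = 3)
  # oracle: direct SVD of the standardized matrix
  phat <- colMeans(g) / 2
  keep <- phat > 0 & phat < 1
  X <- scale(g[, keep], center = 2 * phat[keep],
             scale = sqrt(phat[keep] * (1 - phat[keep])))
  sv <- svd(X)
  for (c in 1:3) {
    expect_equal(abs(cor(ef$projections[, c], sv$u[, c])), 1,
                 tolerance = 1e-8)
    expect_equal(ef$eigenvalues[c], sv$d[c]^2 / sum(keep), tolerance = 1e-8)
  }
  expect_error(eigen_ancestry(matrix(1L, 3, 4)), "monomorphic")
})

test_that("eigen-ancestry weighting matches duplication and coding flips", {
  withr::with_seed(68, {
    g <- matrix(rbinom(10 * 40, 2, runif(40, 0.2, 0.8)), 10, 40, byrow = TRUE)
  })
  w <- c(1, 2, 1, 3, 1, 1, 2, 1, 1, 2)
  reps <- rep(1:10, w)
  fw <- eigen_ancestry(g, 2, weights = w)
  fd <- eigen_ancestry(g[reps, ], 2)
  expect_equal(fw$eigenvalues[1:5], fd$eigenvalues[1:5], tolerance = 1e-8)

  # locus order is irrelevant
  perm <- sample(40)
  fp <- eigen_ancestry(g[, perm], 2)
  expect_equal(abs(cor(fp$projections[, 1],
                       eigen_ancestry(g, 2)$projections[, 1])), 1,
               tolerance = 1e-9)
  # flipping one locus's allele coding leaves projections unchanged
  gf <- g
  gf[, 7] <- 2L - gf[, 7]
  ff <- eigen_ancestry(gf, 2)
  expect_equal(abs(cor(ff$projections[, 1],
                       eigen_ancestry(g, 2)$projections[, 1])), 1,
               tolerance = 1e-9)
})

test_that("cluster alignment fixes orientation without changing accuracy", {
  withr::with_seed(69, {
    theta <- runif(12)
    q1 <- pmin(pmax(theta + rnorm(12, 0, 0.05), 0.01), 0.99)
  })
  fit <- structure(list(Q = cbind(q1, 1 - q1), P = matrix(0.5, 2, 3), K = 2),
                   class = "admixture_fit")
  aligned <- align_clusters(fit, theta)
  expect_equal(aligned$alignment, c(1, 2))          # already oriented
  swapped <- fit
  swapped$Q <- fit$Q[, 2:1]
  back <- align_clusters(swapped, theta)
  expect_equal(back$alignment, c(2, 1))             # swap undone
  expect_equal(back$Q, fit$Q, ignore_attr = TRUE)
  # r^2 is blind to the alignment
  expect_equal(squared_correlation(theta, swapped$Q[, 1]),
               squared_correlation(theta, back$Q[, 1]))
})
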