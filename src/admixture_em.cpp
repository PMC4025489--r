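#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Admixture-likelihood EM core for genotypes in {0,1,2} (9 = missing).
//
// Model: pi_ij = sum_k q_ik p_kj; weighted binomial log-likelihood
//   l = sum_i w_i sum_j [ g_ij log(pi_ij) + (2 - g_ij) log(1 - pi_ij) ].
// EM responsibilities: a_ijk = q_ik p_kj / pi_ij for the alternate allele,
// b_ijk = q_ik (1 - p_kj) / (1 - pi_ij) for the reference allele.
// Updates: q_ik <- (1/(2 M_i)) sum_j [g a + (2-g) b]   (M_i non-missing loci;
//          skipped for pinned individuals, whose q row stays a vertex),
//          p_kj <- sum_i w_i g a / sum_i w_i [g a + (2-g) b]
//          (pinned individuals still contribute to p).
// Individual weights w multiply per-individual likelihood contributions, so
// an integer weight m is algebraically identical to m duplicated rows.

static inline double clampp(double x, double eps) {
  if (x < eps) return eps;
  if (x > 1.0 - eps) return 1.0 - eps;
  return x;
}

// One EM sweep: returns the log-likelihood at (q, p) and writes the updated
// parameters into (qnew, pnew).
static double em_sweep(const IntegerMatrix& G,
                       const NumericMatrix& q, const NumericMatrix& p,
                       const NumericVector& w, const IntegerVector& pinned,
                       const IntegerVector& nonmiss,
                       NumericMatrix& qnew, NumericMatrix& pnew,
                       double eps) {
  const int N = G.nrow(), M = G.ncol(), K = q.ncol();
  std::vector<double> qnum((size_t)N * K, 0.0);
  std::vector<double> pnum((size_t)K * M, 0.0);
  std::vector<double> pden((size_t)K * M, 0.0);
  const int* Gp = INTEGER(G);
  const double* qp = REAL(q);
  const double* pp = REAL(p);
  const double* wp = REAL(w);
  // Deferred-log likelihood accumulation: per-row products of the binomial
  // terms pi^g (1-pi)^(2-g), flushed to a log before underflow. Keeping the
  // accumulator per row makes the weighted sum match the duplicated-row sum.
  std::vector<double> rowprod(N, 1.0), rowll(N, 0.0);

  if (K == 2) {  // the common two-ancestral-population case, unrolled
    const double* q1 = qp;
    const double* q2 = qp + N;
    double* qn1 = &qnum[0];
    double* qn2 = &qnum[(size_t)N];
    for (int j = 0; j < M; ++j) {
      const int* gcol = Gp + (size_t)j * N;
      const double p1 = pp[(size_t)j * 2], p2 = pp[(size_t)j * 2 + 1];
      double pn1 = 0.0, pn2 = 0.0, pd1 = 0.0, pd2 = 0.0;
      for (int i = 0; i < N; ++i) {
        const int g = gcol[i];
        if (g == 9) continue;
        const double qi1 = q1[i], qi2 = q2[i];
        double pi = qi1 * p1 + qi2 * p2;
        pi = clampp(pi, eps);
        const double omp = 1.0 - pi;
        const double term = (g == 0) ? omp * omp : (g == 2 ? pi * pi : pi * omp);
        rowprod[i] *= term;
        if (rowprod[i] < 1e-280) {
          rowll[i] += std::log(rowprod[i]);
          rowprod[i] = 1.0;
        }
        const double wi = wp[i];
        const double ga = g / pi, gb = (2 - g) / omp;
        const double a1 = qi1 * p1 * ga, a2 = qi2 * p2 * ga;
        const double b1 = qi1 * (1.0 - p1) * gb, b2 = qi2 * (1.0 - p2) * gb;
        qn1[i] += a1 + b1;
        qn2[i] += a2 + b2;
        pn1 += wi * a1;
        pn2 += wi * a2;
        pd1 += wi * (a1 + b1);
        pd2 += wi * (a2 + b2);
      }
      pnum[(size_t)j * 2] = pn1;
      pnum[(size_t)j * 2 + 1] = pn2;
      pden[(size_t)j * 2] = pd1;
      pden[(size_t)j * 2 + 1] = pd2;
    }
  } else {
    std::vector<double> pcol(K);
    for (int j = 0; j < M; ++j) {
      const int* gcol = Gp + (size_t)j * N;
      for (int k = 0; k < K; ++k) pcol[k] = pp[(size_t)j * K + k];
      double* pnj = &pnum[(size_t)j * K];
      double* pdj = &pden[(size_t)j * K];
      for (int i = 0; i < N; ++i) {
        const int g = gcol[i];
        if (g == 9) continue;
        double pi = 0.0;
        for (int k = 0; k < K; ++k) pi += qp[(size_t)k * N + i] * pcol[k];
        pi = clampp(pi, eps);
        const double omp = 1.0 - pi;
        const double term = (g == 0) ? omp * omp : (g == 2 ? pi * pi : pi * omp);
        rowprod[i] *= term;
        if (rowprod[i] < 1e-280) {
          rowll[i] += std::log(rowprod[i]);
          rowprod[i] = 1.0;
        }
        const double wi = wp[i];
        const double ga = g / pi, gb = (2 - g) / omp;
        for (int k = 0; k < K; ++k) {
          const double qa = qp[(size_t)k * N + i] * pcol[k] * ga;
          const double qb = qp[(size_t)k * N + i] * (1.0 - pcol[k]) * gb;
          qnum[(size_t)k * N + i] += qa + qb;
          pnj[k] += wi * qa;
          pdj[k] += wi * (qa + qb);
        }
      }
    }
  }
  double ll = 0.0;
  for (int i = 0; i < N; ++i) ll += wp[i] * (rowll[i] + std::log(rowprod[i]));
  for (int i = 0; i < N; ++i) {
    if (pinned[i] > 0) {
      for (int k = 0; k < K; ++k) qnew(i, k) = (k == pinned[i] - 1) ? 1.0 : 0.0;
    } else {
      // divide by the realized responsibility mass (equals 2 * M_i up to
      // the pi clamp) so q rows stay exactly on the simplex even when a
      // frequency sits at the clamp boundary
      double denom = 0.0;
      for (int k = 0; k < K; ++k) denom += qnum[(size_t)k * N + i];
      for (int k = 0; k < K; ++k)
        qnew(i, k) = denom > 0 ? qnum[(size_t)k * N + i] / denom : q(i, k);
    }
  }
  for (int j = 0; j < M; ++j) {
    for (int k = 0; k < K; ++k) {
      const double den = pden[(size_t)j * K + k];
      pnew(k, j) = den > 0 ? clampp(pnum[(size_t)j * K + k] / den, eps)
                           : p(k, j);
    }
  }
  return ll;
}

// [[Rcpp::export]]
double admix_loglik_cpp(const IntegerMatrix& G, const NumericMatrix& q,
                        const NumericMatrix& p, const NumericVector& w,
                        double eps) {
  const int N = G.nrow(), M = G.ncol(), K = q.ncol();
  const int* Gp = INTEGER(G);
  const double* qp = REAL(q);
  const double* pp = REAL(p);
  std::vector<double> rowprod(N, 1.0), rowll(N, 0.0);
  for (int j = 0; j < M; ++j) {
    const int* gcol = Gp + (size_t)j * N;
    for (int i = 0; i < N; ++i) {
      const int g = gcol[i];
      if (g == 9) continue;
      double pi = 0.0;
      for (int k = 0; k < K; ++k) pi += qp[(size_t)k * N + i] * pp[(size_t)j * K + k];
      pi = clampp(pi, eps);
      const double omp = 1.0 - pi;
      const double term = (g == 0) ? omp * omp : (g == 2 ? pi * pi : pi * omp);
      rowprod[i] *= term;
      if (rowprod[i] < 1e-280) {
        rowll[i] += std::log(rowprod[i]);
        rowprod[i] = 1.0;
      }
    }
  }
  double ll = 0.0;
  for (int i = 0; i < N; ++i) ll += w[i] * (rowll[i] + std::log(rowprod[i]));
  return ll;
}

// Squared step norms with individual weights on the q block, so that an
// integer-weighted run and the equivalent duplicated-row run take identical
// accelerated steps.
static double step_norm2(const NumericMatrix& x1, const NumericMatrix& x0,
                         const NumericVector* w) {
  double s = 0.0;
  const int n = x1.nrow(), m = x1.ncol();
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) {
      const double d = x1(i, j) - x0(i, j);
      s += (w ? (*w)[i] : 1.0) * d * d;
    }
  return s;
}

static void project_q(NumericMatrix& q, const IntegerVector& pinned,
                      double eps) {
  const int N = q.nrow(), K = q.ncol();
  for (int i = 0; i < N; ++i) {
    if (pinned[i] > 0) {
      for (int k = 0; k < K; ++k) q(i, k) = (k == pinned[i] - 1) ? 1.0 : 0.0;
      continue;
    }
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      if (q(i, k) < eps) q(i, k) = eps;
      s += q(i, k);
    }
    for (int k = 0; k < K; ++k) q(i, k) /= s;
  }
}

static void project_p(NumericMatrix& p, double eps) {
  const int K = p.nrow(), M = p.ncol();
  for (int j = 0; j < M; ++j)
    for (int k = 0; k < K; ++k) p(k, j) = clampp(p(k, j), eps);
}

// [[Rcpp::export]]
List admix_em_cpp(const IntegerMatrix& G, NumericMatrix Q0, NumericMatrix P0,
                  const NumericVector& w, const IntegerVector& pinned,
                  double tol, int max_iter, double eps, bool accelerate) {
  const int N = G.nrow(), M = G.ncol(), K = Q0.ncol();
  IntegerVector nonmiss(N);
  for (int i = 0; i < N; ++i) {
    int c = 0;
    for (int j = 0; j < M; ++j) if (G(i, j) != 9) ++c;
    nonmiss[i] = c;
  }
  NumericMatrix q = clone(Q0), p = clone(P0);
  NumericMatrix q1(N, K), p1(K, M), q2(N, K), p2(K, M);
  std::vector<double> trace;
  trace.reserve(64);
  bool converged = false;
  int iter = 0;
  double ll_prev = R_NegInf;

  if (!accelerate) {
    while (iter < max_iter) {
      double ll = em_sweep(G, q, p, w, pinned, nonmiss, q1, p1, eps);
      ++iter;
      trace.push_back(ll);
      std::swap(q, q1);
      std::swap(p, p1);
      if (ll - ll_prev < tol && std::isfinite(ll_prev)) {
        converged = true;
        break;
      }
      ll_prev = ll;
    }
  } else {
    while (iter < max_iter) {
      double ll0 = em_sweep(G, q, p, w, pinned, nonmiss, q1, p1, eps);
      ++iter;
      trace.push_back(ll0);
      if (ll0 - ll_prev < tol && std::isfinite(ll_prev)) {
        std::swap(q, q1);
        std::swap(p, p1);
        converged = true;
        break;
      }
      ll_prev = ll0;
      if (iter >= max_iter) { std::swap(q, q1); std::swap(p, p1); break; }
      double ll1 = em_sweep(G, q1, p1, w, pinned, nonmiss, q2, p2, eps);
      ++iter;
      double r2 = step_norm2(q1, q, &w) + step_norm2(p1, p, nullptr);
      // v = (theta2 - theta1) - (theta1 - theta0)
      double v2 = 0.0;
      {
        for (int k = 0; k < K; ++k)
          for (int i = 0; i < N; ++i) {
            const double d = (q2(i, k) - q1(i, k)) - (q1(i, k) - q(i, k));
            v2 += w[i] * d * d;
          }
        for (int j = 0; j < M; ++j)
          for (int k = 0; k < K; ++k) {
            const double d = (p2(k, j) - p1(k, j)) - (p1(k, j) - p(k, j));
            v2 += d * d;
          }
      }
      if (v2 < 1e-30) {  // step already tiny: take the plain double step
        q = clone(q2);
        p = clone(p2);
        continue;
      }
      double alpha = -std::sqrt(r2 / v2);
      if (alpha > -1.0) alpha = -1.0;
      // theta' = theta0 - 2 alpha r + alpha^2 v
      NumericMatrix qs(N, K), ps(K, M);
      for (int k = 0; k < K; ++k)
        for (int i = 0; i < N; ++i) {
          const double r = q1(i, k) - q(i, k);
          const double v = (q2(i, k) - q1(i, k)) - r;
          qs(i, k) = q(i, k) - 2.0 * alpha * r + alpha * alpha * v;
        }
      for (int j = 0; j < M; ++j)
        for (int k = 0; k < K; ++k) {
          const double r = p1(k, j) - p(k, j);
          const double v = (p2(k, j) - p1(k, j)) - r;
          ps(k, j) = p(k, j) - 2.0 * alpha * r + alpha * alpha * v;
        }
      project_q(qs, pinned, eps);
      project_p(ps, eps);
      double lls = admix_loglik_cpp(G, qs, ps, w, eps);
      if (R_finite(lls) && lls >= ll1) {
        q = qs;
        p = ps;
      } else {
        q = clone(q2);
        p = clone(p2);
      }
    }
  }
  double ll_final = admix_loglik_cpp(G, q, p, w, eps);
  trace.push_back(ll_final);
  return List::create(
    _["Q"] = q, _["P"] = p,
    _["loglik_trace"] = NumericVector(trace.begin(), trace.end()),
    _["n_iter"] = iter, _["converged"] = converged
  );
}
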