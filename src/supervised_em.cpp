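#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Supervised admixture estimation: per-individual EM on the binomial
// likelihood  sum_i [ g_i log x_i + (2 - g_i) log(1 - x_i) ],
// x_i = sum_k q_k f_ik, with reference frequencies f fixed (and clipped away
// from 0/1 by the caller). The EM update is
//   q_k <- (1 / 2M) sum_i [ g_i q_k f_ik / x_i + (2 - g_i) q_k (1 - f_ik) / (1 - x_i) ]
// and is monotone in the log-likelihood. The default path accelerates EM by
// squared extrapolation (SQUAREM) with a log-likelihood safeguard: an
// extrapolated point is accepted only if it does not decrease the
// log-likelihood, otherwise the plain double EM step is used, so the iterate
// sequence stays monotone and the fixed points are exactly the EM ones.
// With trace = true the plain (unaccelerated) EM is run and the per-iteration
// log-likelihood trace returned.

// Exact log-likelihood up to the constant binomial coefficients, computed by
// product accumulation with exponent harvesting: one log per ~hundreds of
// SNPs instead of two per SNP.
static double loglik_q(const double* g, const double* F, int M, int K,
                       const double* q) {
  double acc = 1.0;
  long ex = 0;
  int e;
  for (int i = 0; i < M; ++i) {
    double gi = g[i];
    if (ISNAN(gi)) continue;
    double x = 0.0;
    for (int k = 0; k < K; ++k) x += q[k] * F[i + (size_t)k * M];
    double t;
    if (gi == 0.0)      t = (1.0 - x) * (1.0 - x);
    else if (gi == 2.0) t = x * x;
    else                t = x * (1.0 - x);
    acc *= t;
    if (acc < 1e-280) { acc = std::frexp(acc, &e); ex += e; }
  }
  acc = std::frexp(acc, &e);
  ex += e;
  return std::log(acc) + (double)ex * M_LN2;
}

// one EM map application; qn must not alias q
static void em_step(const double* g, const double* F, int M, int K,
                    const double* q, double* qn, int m_obs) {
  for (int k = 0; k < K; ++k) qn[k] = 0.0;
  for (int i = 0; i < M; ++i) {
    double gi = g[i];
    if (ISNAN(gi)) continue;
    double x = 0.0;
    for (int k = 0; k < K; ++k) x += q[k] * F[i + (size_t)k * M];
    double a = gi / x, b = (2.0 - gi) / (1.0 - x);
    for (int k = 0; k < K; ++k) {
      double f = F[i + (size_t)k * M];
      qn[k] += q[k] * (a * f + b * (1.0 - f));
    }
  }
  double denom = 2.0 * m_obs;
  for (int k = 0; k < K; ++k) qn[k] /= denom;
}

// [[Rcpp::export(name = ".em_cohort_cpp")]]
List em_cohort_cpp(NumericMatrix G, NumericMatrix F, double tol, int max_iter,
                   bool trace) {
  const int M = G.nrow(), N = G.ncol(), K = F.ncol();
  if (F.nrow() != M) stop("genotype and frequency matrices disagree on SNP count");

  NumericMatrix Q(N, K);
  NumericVector loglik(N);
  IntegerVector iters(N);
  LogicalVector converged(N);
  List traces(trace ? N : 0);

  std::vector<double> q(K), e1(K), e2(K), qc(K);
  const double* Fp = F.begin();

  for (int n = 0; n < N; ++n) {
    const double* g = &G[(size_t)n * M];
    int m_obs = 0;
    for (int i = 0; i < M; ++i) if (!ISNAN(g[i])) ++m_obs;
    if (m_obs == 0) stop("individual %d has no non-missing genotypes", n + 1);

    for (int k = 0; k < K; ++k) q[k] = 1.0 / K;
    double ll = loglik_q(g, Fp, M, K, q.data());
    int steps = 0;
    bool conv = (K == 1);
    std::vector<double> tr;
    if (trace) tr.push_back(ll);

    if (K > 1 && trace) {
      // plain EM with per-iteration log-likelihood trace
      double ll_prev = ll;
      while (steps < max_iter) {
        em_step(g, Fp, M, K, q.data(), e1.data(), m_obs);
        q.swap(e1);
        ++steps;
        ll = loglik_q(g, Fp, M, K, q.data());
        tr.push_back(ll);
        if (ll - ll_prev < tol) { conv = true; break; }
        ll_prev = ll;
      }
    } else if (K > 1) {
      // SQUAREM-accelerated EM, safeguarded to stay monotone
      while (steps < max_iter) {
        em_step(g, Fp, M, K, q.data(), e1.data(), m_obs);
        em_step(g, Fp, M, K, e1.data(), e2.data(), m_obs);
        steps += 2;
        double nr = 0.0, nv = 0.0;
        for (int k = 0; k < K; ++k) {
          double r = e1[k] - q[k];
          double v = e2[k] - e1[k] - r;
          nr += r * r;
          nv += v * v;
        }
        double ll_new;
        if (nv < 1e-30) {
          q = e2;
          ll_new = loglik_q(g, Fp, M, K, q.data());
        } else {
          double alpha = -std::sqrt(nr / nv);
          if (alpha > -1.0) alpha = -1.0;
          double s = 0.0;
          for (int k = 0; k < K; ++k) {
            double r = e1[k] - q[k];
            double v = e2[k] - e1[k] - r;
            double val = q[k] - 2.0 * alpha * r + alpha * alpha * v;
            qc[k] = val > 1e-9 ? val : 1e-9;
            s += qc[k];
          }
          for (int k = 0; k < K; ++k) qc[k] /= s;
          double llc = loglik_q(g, Fp, M, K, qc.data());
          if (llc >= ll) {
            q = qc;
            ll_new = llc;
          } else {                      // safeguard: fall back to plain EM
            q = e2;
            ll_new = loglik_q(g, Fp, M, K, q.data());
          }
        }
        double dll = ll_new - ll;
        ll = ll_new;
        if (dll < tol) { conv = true; break; }
      }
    }

    double s = 0.0;
    for (int k = 0; k < K; ++k) s += q[k];
    for (int k = 0; k < K; ++k) Q(n, k) = q[k] / s;
    loglik[n] = ll;
    iters[n] = steps;
    converged[n] = conv;
    if (trace) traces[n] = wrap(tr);
  }

  List out = List::create(_["q"] = Q, _["loglik"] = loglik,
                          _["n_iter"] = iters, _["converged"] = converged);
  if (trace) out["trace"] = traces;
  return out;
}
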