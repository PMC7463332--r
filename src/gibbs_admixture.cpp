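// Gibbs sampler for the admixture model on codominant diploid genotypes.
// Data augmentation: each allele copy gets a latent cluster assignment drawn
// proportional to q_ik * p_kla; Q rows are Dirichlet(alpha + counts), P
// slices Dirichlet(lambda + counts) under the independent-frequency model or
// Dirichlet((1-F_k)/F_k * pA + counts) under the correlated F-model, whose
// ancestral frequencies pA and drift parameters F_k are updated by
// Metropolis-Hastings. Uses R's RNG so results are reproducible via set.seed.
#include <Rcpp.h>
using namespace Rcpp;

static void rdirichlet_inplace(double *out, const double *alpha, int m) {
  double s = 0.0;
  for (int a = 0; a < m; ++a) {
    out[a] = R::rgamma(alpha[a] > 1e-8 ? alpha[a] : 1e-8, 1.0);
    s += out[a];
  }
  if (s <= 0.0) {
    for (int a = 0; a < m; ++a) out[a] = 1.0 / m;
  } else {
    for (int a = 0; a < m; ++a) out[a] /= s;
  }
}

// log Dirichlet(x; alpha) density
static double ldirichlet(const double *x, const double *alpha, int m) {
  double s = 0.0, lg = 0.0, ll = 0.0;
  for (int a = 0; a < m; ++a) {
    s += alpha[a];
    lg += R::lgammafn(alpha[a] > 1e-10 ? alpha[a] : 1e-10);
    ll += (alpha[a] - 1.0) * std::log(x[a] > 1e-300 ? x[a] : 1e-300);
  }
  return R::lgammafn(s) - lg + ll;
}

// [[Rcpp::export(name = ".gibbs_admixture_cpp")]]
List gibbs_admixture_cpp(IntegerMatrix g1, IntegerMatrix g2,
                         IntegerVector nAlleles, int K, int burnin, int iters,
                         double alpha, double lambda, int correlated,
                         int infer_alpha) {
  const int n = g1.nrow(), L = g1.ncol();
  int Amax = 0;
  for (int l = 0; l < L; ++l) if (nAlleles[l] > Amax) Amax = nAlleles[l];
  const int total = burnin + iters;

  std::vector<double> Q(n * K, 1.0 / K);
  std::vector<double> P(K * L * Amax, 0.0);
  std::vector<double> pA(L * Amax, 0.0);
  std::vector<double> Fk(K, 0.05);
  std::vector<double> buf(Amax), abuf(Amax);

  // init P (and pA) from flat Dirichlets
  for (int l = 0; l < L; ++l) {
    const int A = nAlleles[l];
    for (int a = 0; a < A; ++a) abuf[a] = 1.0;
    rdirichlet_inplace(&pA[l * Amax], abuf.data(), A);
    for (int k = 0; k < K; ++k)
      rdirichlet_inplace(&P[(k * L + l) * Amax], abuf.data(), A);
  }

  std::vector<double> countQ(n * K), countP(K * L * Amax);
  std::vector<double> Qsum(n * K, 0.0), Psum(K * L * Amax, 0.0);
  NumericVector trace(total);
  std::vector<double> w(K);

  for (int it = 0; it < total; ++it) {
    std::fill(countQ.begin(), countQ.end(), 0.0);
    std::fill(countP.begin(), countP.end(), 0.0);
    double loglik = 0.0;

    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int copy = 0; copy < 2; ++copy) {
          const int a = (copy == 0 ? g1(i, l) : g2(i, l));
          if (a <= 0) continue;
          double s = 0.0;
          for (int k = 0; k < K; ++k) {
            w[k] = Q[i * K + k] * P[(k * L + l) * Amax + (a - 1)];
            s += w[k];
          }
          if (!(s > 0.0)) { s = 0.0; for (int k = 0; k < K; ++k) { w[k] = 1.0 / K; s += w[k]; } }
          loglik += std::log(s);
          double u = R::unif_rand() * s;
          int k = 0;
          double acc = w[0];
          while (k < K - 1 && u > acc) acc += w[++k];
          countQ[i * K + k] += 1.0;
          countP[(k * L + l) * Amax + (a - 1)] += 1.0;
        }
      }
    }
    trace[it] = loglik;

    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < K; ++k) abuf[k] = alpha + countQ[i * K + k];
      rdirichlet_inplace(&Q[i * K], abuf.data(), K);
    }

    if (infer_alpha && K > 1) {
      // MH update of the symmetric ancestry Dirichlet parameter, uniform
      // prior on (0.001, 10), normal random-walk proposal (STRUCTURE-style)
      double prop = alpha + 0.05 * R::norm_rand();
      if (prop > 0.001 && prop < 10.0) {
        double S = 0.0;
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k) {
            double q = Q[i * K + k];
            S += std::log(q > 1e-300 ? q : 1e-300);
          }
        double logr = n * (R::lgammafn(K * prop) - K * R::lgammafn(prop)) -
                      n * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha)) +
                      (prop - alpha) * S;
        if (std::log(R::unif_rand()) < logr) alpha = prop;
      }
    }

    for (int k = 0; k < K; ++k) {
      const double ck = (1.0 - Fk[k]) / Fk[k];
      for (int l = 0; l < L; ++l) {
        const int A = nAlleles[l];
        for (int a = 0; a < A; ++a) {
          const double prior = correlated ? ck * pA[l * Amax + a] : lambda;
          abuf[a] = prior + countP[(k * L + l) * Amax + a];
        }
        rdirichlet_inplace(&P[(k * L + l) * Amax], abuf.data(), A);
      }
    }

    if (correlated) {
      // MH update of ancestral frequencies, per locus
      const double delta = 200.0;
      for (int l = 0; l < L; ++l) {
        const int A = nAlleles[l];
        double *cur = &pA[l * Amax];
        for (int a = 0; a < A; ++a) abuf[a] = delta * cur[a] + 0.05;
        rdirichlet_inplace(buf.data(), abuf.data(), A);
        double logr = 0.0;
        // prior Dirichlet(lambda)
        for (int a = 0; a < A; ++a)
          logr += (lambda - 1.0) * (std::log(buf[a] > 1e-300 ? buf[a] : 1e-300) -
                                    std::log(cur[a] > 1e-300 ? cur[a] : 1e-300));
        // likelihood of P slices
        std::vector<double> apro(A), acur(A);
        for (int k = 0; k < K; ++k) {
          const double ck = (1.0 - Fk[k]) / Fk[k];
          for (int a = 0; a < A; ++a) { apro[a] = ck * buf[a]; acur[a] = ck * cur[a]; }
          logr += ldirichlet(&P[(k * L + l) * Amax], apro.data(), A) -
                  ldirichlet(&P[(k * L + l) * Amax], acur.data(), A);
        }
        // Hastings correction
        std::vector<double> qfwd(A), qrev(A);
        for (int a = 0; a < A; ++a) {
          qfwd[a] = delta * cur[a] + 0.05;
          qrev[a] = delta * buf[a] + 0.05;
        }
        logr += ldirichlet(cur, qrev.data(), A) - ldirichlet(buf.data(), qfwd.data(), A);
        if (std::log(R::unif_rand()) < logr)
          for (int a = 0; a < A; ++a) cur[a] = buf[a];
      }
      // MH update of drift parameters, uniform prior on (0.001, 0.5)
      for (int k = 0; k < K; ++k) {
        const double lo = 0.001, hi = 0.5;
        double prop = Fk[k] + 0.02 * (R::unif_rand() - 0.5);
        if (prop <= lo || prop >= hi) continue;
        const double ckn = (1.0 - prop) / prop, cko = (1.0 - Fk[k]) / Fk[k];
        double logr = 0.0;
        std::vector<double> an(Amax), ao(Amax);
        for (int l = 0; l < L; ++l) {
          const int A = nAlleles[l];
          for (int a = 0; a < A; ++a) {
            an[a] = ckn * pA[l * Amax + a];
            ao[a] = cko * pA[l * Amax + a];
          }
          logr += ldirichlet(&P[(k * L + l) * Amax], an.data(), A) -
                  ldirichlet(&P[(k * L + l) * Amax], ao.data(), A);
        }
        if (std::log(R::unif_rand()) < logr) Fk[k] = prop;
      }
    }

    if (it >= burnin) {
      for (size_t j = 0; j < Qsum.size(); ++j) Qsum[j] += Q[j];
      for (size_t j = 0; j < Psum.size(); ++j) Psum[j] += P[j];
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix Qmean(n, K);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += Qsum[i * K + k];
    for (int k = 0; k < K; ++k) Qmean(i, k) = Qsum[i * K + k] / (s > 0 ? s : 1);
  }
  NumericVector Pmean(K * L * Amax);
  for (int j = 0; j < K * L * Amax; ++j) Pmean[j] = Psum[j] / iters;
  Pmean.attr("dim") = IntegerVector::create(Amax, L, K);

  return List::create(_["Q"] = Qmean, _["P"] = Pmean, _["trace"] = trace,
                      _["F"] = NumericVector(Fk.begin(), Fk.end()),
                      _["alpha_final"] = alpha);
}
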