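// Gibbs sampler for the Bayesian admixture model with correlated allele
// frequencies (ancestral frequency per locus, per-cluster drift F_k).
// Genotypes are biallelic dosages 0/1/2 with NA for missing. Latent
// allele-copy origins are sampled per copy; Q rows from a Dirichlet;
// cluster frequencies from their conjugate Beta; ancestral frequencies,
// drift parameters and the admixture concentration alpha by
// random-walk Metropolis.
#include <Rcpp.h>
using namespace Rcpp;

static inline double clamp01(double x, double eps) {
  if (x < eps) return eps;
  if (x > 1.0 - eps) return 1.0 - eps;
  return x;
}

// [[Rcpp::export]]
List admixture_gibbs_cpp(IntegerMatrix G, int K, int burnin, int nsweeps,
                         int thin, double alphaInit, double fInit,
                         double alphaPropSd, double fPropSd, double paPropSd,
                         double fPriorA, double fPriorB, double alphaMax) {
  const int n = G.nrow(), L = G.ncol();
  const double EPS = 1e-6;

  NumericMatrix Q(n, K), P(K, L);
  NumericVector pA(L);
  NumericVector F(K, fInit);
  double alpha = alphaInit;

  // init: pA from pooled frequencies, P jittered around pA, Q uniform
  for (int l = 0; l < L; ++l) {
    double s = 0; int c = 0;
    for (int i = 0; i < n; ++i)
      if (G(i, l) != NA_INTEGER) { s += G(i, l); c += 2; }
    pA[l] = clamp01(c ? s / c : 0.5, 0.01);
    for (int k = 0; k < K; ++k)
      P(k, l) = clamp01(pA[l] + 0.05 * (unif_rand() - 0.5), EPS);
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Q(i, k) = 1.0 / K;

  std::vector<double> m(n * K), c1(K * L), c2(K * L), w(K);

  const int total = burnin + nsweeps;
  const int nKeep = nsweeps / thin;
  NumericVector qKeep(std::max(nKeep, 1) * n * K);
  NumericVector lnLTrace(nsweeps);
  NumericMatrix fKeep(std::max(nKeep, 1), K);
  NumericVector aKeep(std::max(nKeep, 1));
  NumericMatrix pAcc(K, L);
  int kept = 0, lnlAt = 0;

  for (int sweep = 0; sweep < total; ++sweep) {
    std::fill(m.begin(), m.end(), 0.0);
    std::fill(c1.begin(), c1.end(), 0.0);
    std::fill(c2.begin(), c2.end(), 0.0);

    // 1. allele-copy origins
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        int g = G(i, l);
        if (g == NA_INTEGER) continue;
        // copies of allele 2: g, allele 1: 2-g
        for (int a = 0; a < 2; ++a) {
          bool isSecond = (a < g); // g=0 none, g=1 one, g=2 both
          double wsum = 0;
          for (int k = 0; k < K; ++k) {
            double pk = P(k, l);
            w[k] = Q(i, k) * (isSecond ? pk : 1.0 - pk);
            wsum += w[k];
          }
          double u = unif_rand() * wsum;
          int z = 0;
          while (z < K - 1 && u > w[z]) { u -= w[z]; ++z; }
          m[i * K + z] += 1.0;
          if (isSecond) c2[z * L + l] += 1.0;
          else          c1[z * L + l] += 1.0;
        }
      }
    }

    // 2. Q rows ~ Dirichlet(alpha + m)
    for (int i = 0; i < n; ++i) {
      double s = 0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha + m[i * K + k], 1.0);
        if (g < 1e-300) g = 1e-300;
        Q(i, k) = g; s += g;
      }
      for (int k = 0; k < K; ++k) Q(i, k) = clamp01(Q(i, k) / s, 1e-9);
    }

    // 3. cluster frequencies ~ Beta(prior + counts)
    for (int k = 0; k < K; ++k) {
      double lam = (1.0 - F[k]) / F[k];
      for (int l = 0; l < L; ++l) {
        double a0 = pA[l] * lam, b0 = (1.0 - pA[l]) * lam;
        P(k, l) = clamp01(R::rbeta(a0 + c2[k * L + l], b0 + c1[k * L + l]), EPS);
      }
    }

    // 4. ancestral frequencies: reflected random walk
    for (int l = 0; l < L; ++l) {
      double prop = pA[l] + norm_rand() * paPropSd;
      if (prop < 0) prop = -prop;
      if (prop > 1) prop = 2 - prop;
      prop = clamp01(prop, 1e-4);
      double lr = 0;
      for (int k = 0; k < K; ++k) {
        double lam = (1.0 - F[k]) / F[k];
        lr += R::dbeta(P(k, l), prop * lam, (1 - prop) * lam, 1)
            - R::dbeta(P(k, l), pA[l] * lam, (1 - pA[l]) * lam, 1);
      }
      if (log(unif_rand()) < lr) pA[l] = prop;
    }

    // 5. drift parameters: random walk on logit(F), Beta prior
    for (int k = 0; k < K; ++k) {
      double x = log(F[k] / (1.0 - F[k])) + norm_rand() * fPropSd;
      double fProp = 1.0 / (1.0 + exp(-x));
      fProp = clamp01(fProp, 1e-5);
      double lamP = (1.0 - fProp) / fProp, lamC = (1.0 - F[k]) / F[k];
      double lr = R::dbeta(fProp, fPriorA, fPriorB, 1)
                - R::dbeta(F[k], fPriorA, fPriorB, 1)
                + log(fProp * (1 - fProp)) - log(F[k] * (1 - F[k]));
      for (int l = 0; l < L; ++l)
        lr += R::dbeta(P(k, l), pA[l] * lamP, (1 - pA[l]) * lamP, 1)
            - R::dbeta(P(k, l), pA[l] * lamC, (1 - pA[l]) * lamC, 1);
      if (log(unif_rand()) < lr) F[k] = fProp;
    }

    // 6. admixture concentration: uniform prior on (0, alphaMax)
    if (K > 1) {
      double prop = alpha + norm_rand() * alphaPropSd;
      if (prop > 0 && prop < alphaMax) {
        double slq = 0;
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k) slq += log(Q(i, k));
        double lr = n * (lgamma(K * prop) - K * lgamma(prop))
                  - n * (lgamma(K * alpha) - K * lgamma(alpha))
                  + (prop - alpha) * slq;
        if (log(unif_rand()) < lr) alpha = prop;
      }
    }

    if (sweep >= burnin) {
      // sweep-level ln-likelihood of the genotypes given (P, Q)
      double lnL = 0;
      for (int i = 0; i < n; ++i) {
        for (int l = 0; l < L; ++l) {
          int g = G(i, l);
          if (g == NA_INTEGER) continue;
          double u = 0;
          for (int k = 0; k < K; ++k) u += Q(i, k) * P(k, l);
          u = clamp01(u, 1e-12);
          lnL += (g == 1 ? log(2.0 * u * (1 - u))
                         : (g == 2 ? 2 * log(u) : 2 * log(1 - u)));
        }
      }
      lnLTrace[lnlAt++] = lnL;
      if ((sweep - burnin) % thin == thin - 1 && kept < nKeep) {
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k)
            qKeep[(R_xlen_t)kept * n * K + (R_xlen_t)i * K + k] = Q(i, k);
        for (int k = 0; k < K; ++k) fKeep(kept, k) = F[k];
        aKeep[kept] = alpha;
        ++kept;
      }
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l) pAcc(k, l) += P(k, l);
    }
    if (sweep % 512 == 0) Rcpp::checkUserInterrupt();
  }

  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) pAcc(k, l) /= std::max(nsweeps, 1);

  return List::create(
    _["qSamples"] = qKeep, _["nKept"] = kept,
    _["lnL"] = lnLTrace, _["pMean"] = pAcc,
    _["fSamples"] = fKeep, _["alphaSamples"] = aKeep);
}
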