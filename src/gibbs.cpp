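#include <Rcpp.h>
using namespace Rcpp;

// Admixture-model Gibbs sampler for diploid multilocus genotypes.
//
// geno: n x 2L integer matrix of allele indices (1-based, 0 = missing copy),
// columns (2l-1, 2l) hold the two copies at locus l. Cluster allele
// frequencies carry a flat Dirichlet(1) prior; individual admixture
// proportions q_i a Dirichlet(alpha) prior with fixed alpha. Uses R's RNG so
// set.seed() in R controls the chain.
//
// Returns the per-sweep log-likelihood trace (retained sweeps only) and
// posterior means of q and of the cluster allele frequencies.

static int sample_cat(const double *w, int K, double tot) {
  double u = unif_rand() * tot;
  double acc = 0.0;
  for (int k = 0; k < K; ++k) {
    acc += w[k];
    if (u <= acc) return k;
  }
  return K - 1;
}

// [[Rcpp::export]]
List gibbs_admixture_cpp(IntegerMatrix geno, IntegerVector n_alleles,
                         int K, int burnin, int sweeps, double alpha) {
  const int n = geno.nrow();
  const int L = n_alleles.size();
  if (K < 1) stop("K must be >= 1");

  // allele count offsets so p is stored flat: p[k][off[l] + a]
  std::vector<int> off(L + 1, 0);
  for (int l = 0; l < L; ++l) off[l + 1] = off[l] + n_alleles[l];
  const int Atot = off[L];

  std::vector<std::vector<double>> p(K, std::vector<double>(Atot, 0.0));
  std::vector<std::vector<double>> q(n, std::vector<double>(K, 1.0 / K));
  std::vector<int> z(n * 2 * L, 0);

  // init origins uniformly
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 2 * L; ++c)
      z[i * 2 * L + c] = (int)std::floor(unif_rand() * K);

  std::vector<double> lnl_trace;
  lnl_trace.reserve(sweeps);
  std::vector<std::vector<double>> q_sum(n, std::vector<double>(K, 0.0));
  std::vector<std::vector<double>> p_sum(K, std::vector<double>(Atot, 0.0));
  std::vector<double> w(K);

  for (int it = 0; it < burnin + sweeps; ++it) {
    // p | z : Dirichlet(1 + counts)
    std::vector<std::vector<double>> cnt(K, std::vector<double>(Atot, 0.0));
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a <= 0) continue;
          cnt[z[i * 2 * L + 2 * l + c]][off[l] + a - 1] += 1.0;
        }
      }
    }
    for (int k = 0; k < K; ++k) {
      for (int l = 0; l < L; ++l) {
        double tot = 0.0;
        for (int a = 0; a < n_alleles[l]; ++a) {
          double g = R::rgamma(1.0 + cnt[k][off[l] + a], 1.0);
          p[k][off[l] + a] = g;
          tot += g;
        }
        for (int a = 0; a < n_alleles[l]; ++a) p[k][off[l] + a] /= tot;
      }
    }
    // q | z : Dirichlet(alpha + m_ik)
    for (int i = 0; i < n; ++i) {
      std::vector<double> m(K, 0.0);
      for (int l = 0; l < L; ++l)
        for (int c = 0; c < 2; ++c)
          if (geno(i, 2 * l + c) > 0) m[z[i * 2 * L + 2 * l + c]] += 1.0;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha + m[k], 1.0);
        q[i][k] = g;
        tot += g;
      }
      for (int k = 0; k < K; ++k) q[i][k] /= tot;
    }
    // z | p, q
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a <= 0) continue;
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            w[k] = q[i][k] * p[k][off[l] + a - 1];
            tot += w[k];
          }
          z[i * 2 * L + 2 * l + c] = sample_cat(w.data(), K, tot);
        }
      }
    }
    if (it >= burnin) {
      double lnl = 0.0;
      for (int i = 0; i < n; ++i) {
        for (int l = 0; l < L; ++l) {
          for (int c = 0; c < 2; ++c) {
            int a = geno(i, 2 * l + c);
            if (a <= 0) continue;
            double mix = 0.0;
            for (int k = 0; k < K; ++k) mix += q[i][k] * p[k][off[l] + a - 1];
            lnl += std::log(mix);
          }
        }
      }
      lnl_trace.push_back(lnl);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) q_sum[i][k] += q[i][k];
      for (int k = 0; k < K; ++k)
        for (int a = 0; a < Atot; ++a) p_sum[k][a] += p[k][a];
    }
  }

  NumericMatrix q_mean(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) q_mean(i, k) = q_sum[i][k] / sweeps;
  NumericMatrix p_mean(K, Atot);
  for (int k = 0; k < K; ++k)
    for (int a = 0; a < Atot; ++a) p_mean(k, a) = p_sum[k][a] / sweeps;

  return List::create(_["lnl"] = NumericVector(lnl_trace.begin(), lnl_trace.end()),
                      _["q_mean"] = q_mean,
                      _["p_mean"] = p_mean);
}
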