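#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the admixture model with uncorrelated allele
// frequencies (the classic Bayesian clustering model for multilocus
// genotypes).  Each individual i has admixture proportions q_i ~
// Dirichlet(alpha); each cluster k has, independently at every locus l,
// allele frequencies p_kl ~ Dirichlet(lambda).  Every observed allele copy
// is assigned a cluster of origin z with Pr(z = k) proportional to
// q_ik * p_kl(a); p and q are then redrawn from their Dirichlet full
// conditionals.  Missing calls (coded 0) are skipped everywhere.
//
// Uses the R RNG, so runs are reproducible under set.seed().

static void rdirichlet_into(double *out, const double *shape, int K) {
  double s = 0.0;
  for (int k = 0; k < K; ++k) { out[k] = R::rgamma(shape[k], 1.0); s += out[k]; }
  if (s <= 0.0) { for (int k = 0; k < K; ++k) out[k] = 1.0 / K; return; }
  for (int k = 0; k < K; ++k) out[k] /= s;
}

// [[Rcpp::export]]
List admixture_gibbs_cpp(IntegerMatrix a1, IntegerMatrix a2,
                         IntegerVector n_alleles, int K,
                         int burnin, int iters, int thin,
                         double alpha, double lambda) {
  const int n = a1.nrow(), L = a1.ncol();
  if (K < 1) stop("K must be >= 1");
  if (n < 1) stop("empty genotype table");

  // current state
  NumericMatrix Q(n, K);
  std::fill(Q.begin(), Q.end(), 1.0 / K);
  std::vector<NumericMatrix> P(L);
  for (int l = 0; l < L; ++l) {
    P[l] = NumericMatrix(K, n_alleles[l]);
    std::fill(P[l].begin(), P[l].end(), 1.0 / n_alleles[l]);
  }

  // accumulators
  NumericMatrix Qsum(n, K);
  std::vector<NumericMatrix> Psum(L);
  for (int l = 0; l < L; ++l) Psum[l] = NumericMatrix(K, n_alleles[l]);
  std::vector<double> trace;
  int n_kept = 0;

  std::vector<double> w(K), shape(std::max(K, 1));
  std::vector<double> indCounts((size_t)n * K);
  const int total = burnin + iters;

  GetRNGstate();
  for (int it = 0; it < total; ++it) {
    // reset counts
    std::fill(indCounts.begin(), indCounts.end(), 0.0);
    std::vector<std::vector<double> > clCounts(L);
    for (int l = 0; l < L; ++l)
      clCounts[l].assign((size_t)K * n_alleles[l], 0.0);

    bool record = (it >= burnin) && ((it - burnin) % thin == 0);
    double ll = 0.0;

    // (i) sample cluster of origin for every allele copy
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int copy = 0; copy < 2; ++copy) {
          int a = (copy == 0) ? a1(i, l) : a2(i, l);
          if (a == NA_INTEGER || a <= 0) continue;
          double s = 0.0;
          for (int k = 0; k < K; ++k) {
            w[k] = Q(i, k) * P[l](k, a - 1);
            s += w[k];
          }
          if (record) ll += std::log(s > 0 ? s : 1e-300);
          int z = K - 1;
          if (s > 0) {
            double u = unif_rand() * s, acc = 0.0;
            for (int k = 0; k < K; ++k) {
              acc += w[k];
              if (u <= acc) { z = k; break; }
            }
          } else {
            z = (int)(unif_rand() * K); if (z >= K) z = K - 1;
          }
          indCounts[(size_t)i * K + z] += 1.0;
          clCounts[l][(size_t)z * n_alleles[l] + (a - 1)] += 1.0;
        }
      }
    }

    // (ii) cluster allele frequencies, independently per cluster x locus
    for (int l = 0; l < L; ++l) {
      int A = n_alleles[l];
      std::vector<double> sh(A), pr(A);
      for (int k = 0; k < K; ++k) {
        for (int a = 0; a < A; ++a)
          sh[a] = lambda + clCounts[l][(size_t)k * A + a];
        rdirichlet_into(&pr[0], &sh[0], A);
        for (int a = 0; a < A; ++a) P[l](k, a) = pr[a];
      }
    }

    // (iii) admixture proportions
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < K; ++k)
        shape[k] = alpha + indCounts[(size_t)i * K + k];
      if (K == 1) { Q(i, 0) = 1.0; continue; }
      std::vector<double> qi(K);
      rdirichlet_into(&qi[0], &shape[0], K);
      for (int k = 0; k < K; ++k) Q(i, k) = qi[k];
    }

    if (record) {
      trace.push_back(ll);
      ++n_kept;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (int l = 0; l < L; ++l)
        for (int k = 0; k < K; ++k)
          for (int a = 0; a < n_alleles[l]; ++a)
            Psum[l](k, a) += P[l](k, a);
    }
  }
  PutRNGstate();

  if (n_kept == 0) stop("no recorded iterations: increase iters or lower thin");
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) /= n_kept;
  List Pout(L);
  for (int l = 0; l < L; ++l) {
    for (int k = 0; k < K; ++k)
      for (int a = 0; a < n_alleles[l]; ++a) Psum[l](k, a) /= n_kept;
    Pout[l] = Psum[l];
  }
  return List::create(_["Q"] = Qsum, _["P"] = Pout,
                      _["loglik_trace"] = NumericVector(trace.begin(), trace.end()),
                      _["n_kept"] = n_kept);
}
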