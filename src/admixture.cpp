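#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gibbs sampler for the diploid admixture model (no linkage, no location
// prior). Gene-copy cluster origins, cluster allele frequencies P and
// individual ancestry Q are updated by their full conditionals; the
// admixture parameter alpha (shared across individuals, uniform(0,10)
// prior) and, under the correlated-frequency model, the per-cluster drift
// parameter F (uniform(0,1) prior) move by Metropolis steps.
//
// geno: N x 2L matrix of 0-based allele codes, -1 = missing.
// p_anc: L x maxA pooled ("ancestral") allele frequencies.
// Returns posterior means of Q and P, the per-sweep log-likelihood trace,
// and posterior means of alpha and F.

static double rdirichlet_row(std::vector<double> &out, const std::vector<double> &shape) {
  double tot = 0.0;
  for (size_t i = 0; i < shape.size(); ++i) {
    double g = R::rgamma(shape[i], 1.0);
    if (g < 1e-300) g = 1e-300;
    out[i] = g;
    tot += g;
  }
  for (size_t i = 0; i < shape.size(); ++i) out[i] /= tot;
  return tot;
}

// [[Rcpp::export(name = ".admixture_gibbs_cpp")]]
List admixture_gibbs_cpp(IntegerMatrix geno, IntegerVector n_alleles, int K,
                         int burnin, int steps, double alpha_init,
                         bool correlated, NumericMatrix p_anc, double lambda,
                         double alpha_prop_sd, double f_prop_sd) {
  const int N = geno.nrow();
  const int L = n_alleles.size();
  const int maxA = p_anc.ncol();

  // P[k][l*maxA + a], Q[i*K + k]
  std::vector<double> P((size_t)K * L * maxA, 0.0);
  std::vector<double> Q((size_t)N * K, 1.0 / K);
  std::vector<double> Pmean((size_t)K * L * maxA, 0.0);
  std::vector<double> Qmean((size_t)N * K, 0.0);
  std::vector<double> F(K, 0.5);
  std::vector<double> Fmean(K, 0.0);
  double alpha = alpha_init, alpha_mean = 0.0;

  // init P at pooled frequencies (jittered by the first Dirichlet update)
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l)
      for (int a = 0; a < n_alleles[l]; ++a)
        P[((size_t)k * L + l) * maxA + a] = p_anc(l, a);

  std::vector<int> nik((size_t)N * K);        // copies of i assigned to k
  std::vector<int> mkla((size_t)K * L * maxA); // cluster-allele counts
  std::vector<double> probs(K), dirsh(std::max(K, maxA)), dirout(std::max(K, maxA));
  NumericVector lnl_trace(steps);
  int n_kept = 0;

  for (int it = 0; it < burnin + steps; ++it) {
    // --- sample origins z for every observed gene copy
    std::fill(nik.begin(), nik.end(), 0);
    std::fill(mkla.begin(), mkla.end(), 0);
    for (int i = 0; i < N; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a < 0) continue;
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            probs[k] = Q[(size_t)i * K + k] * P[((size_t)k * L + l) * maxA + a];
            tot += probs[k];
          }
          double u = R::unif_rand() * tot, cum = 0.0;
          int z = K - 1;
          for (int k = 0; k < K; ++k) { cum += probs[k]; if (u <= cum) { z = k; break; } }
          nik[(size_t)i * K + z]++;
          mkla[((size_t)z * L + l) * maxA + a]++;
        }
      }
    }

    // --- update P | z
    for (int k = 0; k < K; ++k) {
      for (int l = 0; l < L; ++l) {
        int A = n_alleles[l];
        for (int a = 0; a < A; ++a) {
          double prior = correlated
            ? p_anc(l, a) * (1.0 - F[k]) / F[k]
            : lambda;
          dirsh[a] = prior + mkla[((size_t)k * L + l) * maxA + a];
        }
        std::vector<double> sh(dirsh.begin(), dirsh.begin() + A);
        std::vector<double> out(A);
        rdirichlet_row(out, sh);
        for (int a = 0; a < A; ++a) P[((size_t)k * L + l) * maxA + a] = out[a];
      }
    }

    // --- update F_k | P (correlated model)
    if (correlated && K > 1) {
      for (int k = 0; k < K; ++k) {
        double fprop = F[k] + R::norm_rand() * f_prop_sd;
        if (fprop <= 0.0 || fprop >= 1.0) continue;
        double ll_old = 0.0, ll_new = 0.0;
        for (int l = 0; l < L; ++l) {
          int A = n_alleles[l];
          double s_old = 0.0, s_new = 0.0;
          for (int a = 0; a < A; ++a) {
            double th_old = p_anc(l, a) * (1.0 - F[k]) / F[k];
            double th_new = p_anc(l, a) * (1.0 - fprop) / fprop;
            double lp = std::log(P[((size_t)k * L + l) * maxA + a]);
            ll_old += (th_old - 1.0) * lp - R::lgammafn(th_old);
            ll_new += (th_new - 1.0) * lp - R::lgammafn(th_new);
            s_old += th_old; s_new += th_new;
          }
          ll_old += R::lgammafn(s_old);
          ll_new += R::lgammafn(s_new);
        }
        if (std::log(R::unif_rand()) < ll_new - ll_old) F[k] = fprop;
      }
    }

    // --- update Q | z
    for (int i = 0; i < N; ++i) {
      std::vector<double> sh(K), out(K);
      for (int k = 0; k < K; ++k) sh[k] = alpha + nik[(size_t)i * K + k];
      rdirichlet_row(out, sh);
      for (int k = 0; k < K; ++k) Q[(size_t)i * K + k] = out[k];
    }

    // --- update alpha | Q (Metropolis, uniform(0, 10) prior)
    if (K > 1) {
      double aprop = alpha + R::norm_rand() * alpha_prop_sd;
      if (aprop > 0.0 && aprop < 10.0) {
        double ll = 0.0;
        for (int i = 0; i < N; ++i) {
          double slq = 0.0;
          for (int k = 0; k < K; ++k) slq += std::log(Q[(size_t)i * K + k]);
          ll += (R::lgammafn(K * aprop) - K * R::lgammafn(aprop) + (aprop - 1.0) * slq)
              - (R::lgammafn(K * alpha) - K * R::lgammafn(alpha) + (alpha - 1.0) * slq);
        }
        if (std::log(R::unif_rand()) < ll) alpha = aprop;
      }
    }

    // --- log-likelihood of the data given current Q, P
    if (it >= burnin) {
      double lnl = 0.0;
      for (int i = 0; i < N; ++i) {
        for (int l = 0; l < L; ++l) {
          for (int c = 0; c < 2; ++c) {
            int a = geno(i, 2 * l + c);
            if (a < 0) continue;
            double s = 0.0;
            for (int k = 0; k < K; ++k)
              s += Q[(size_t)i * K + k] * P[((size_t)k * L + l) * maxA + a];
            lnl += std::log(s);
          }
        }
      }
      lnl_trace[it - burnin] = lnl;
      for (size_t j = 0; j < Q.size(); ++j) Qmean[j] += Q[j];
      for (size_t j = 0; j < P.size(); ++j) Pmean[j] += P[j];
      for (int k = 0; k < K; ++k) Fmean[k] += F[k];
      alpha_mean += alpha;
      ++n_kept;
    }
  }

  NumericMatrix Qout(N, K);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k)
      Qout(i, k) = Qmean[(size_t)i * K + k] / n_kept;
  List Pout(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix pm(K, n_alleles[l]);
    for (int k = 0; k < K; ++k)
      for (int a = 0; a < n_alleles[l]; ++a)
        pm(k, a) = Pmean[((size_t)k * L + l) * maxA + a] / n_kept;
    Pout[l] = pm;
  }
  NumericVector fout(K);
  for (int k = 0; k < K; ++k) fout[k] = Fmean[k] / n_kept;
  return List::create(
    _["Q"] = Qout, _["P"] = Pout, _["lnl"] = lnl_trace,
    _["alpha"] = alpha_mean / n_kept, _["F"] = fout
  );
}

// Markov-chain exact test of Hardy-Weinberg proportions on a
// multi-allelic genotype table. The chain operates on the underlying
// arrangement of 2N gene copies into N ordered pairs: swapping two
// uniformly chosen copies is a symmetric, always-accepted move, and the
// uniform distribution over arrangements induces exactly the Levene
// conditional distribution of genotype tables given the allele counts.
// The p-value is the fraction of visited tables no more probable than
// the observed one.
//
// g: k x k genotype count matrix (only the lower triangle i >= j is used).

static inline double tab_logprob(const std::vector<int> &g, int k) {
  // log conditional probability up to a constant: H*log2 - sum log(g_ij!)
  double lp = 0.0;
  for (int i = 0; i < k; ++i)
    for (int j = 0; j <= i; ++j) {
      int c = g[i * k + j];
      lp -= R::lgammafn(c + 1.0);
      if (i != j) lp += c * M_LN2;
    }
  return lp;
}

// [[Rcpp::export(name = ".hwe_mcmc_cpp")]]
double hwe_mcmc_cpp(IntegerMatrix gmat, int steps, int dememorisation) {
  const int k = gmat.nrow();
  std::vector<int> g(k * k, 0);
  int N = 0;
  for (int i = 0; i < k; ++i)
    for (int j = 0; j <= i; ++j) { g[i * k + j] = gmat(i, j); N += gmat(i, j); }

  const double lp_obs = tab_logprob(g, k);
  double lp_cur = lp_obs;

  // explicit arrangement: copies 2t and 2t+1 belong to individual t
  std::vector<int> a(2 * N);
  {
    int pos = 0;
    for (int i = 0; i < k; ++i)
      for (int j = 0; j <= i; ++j)
        for (int c = 0; c < g[i * k + j]; ++c) { a[pos++] = i; a[pos++] = j; }
  }
  auto cell = [&](int x, int y) { return x >= y ? x * k + y : y * k + x; };

  long long hits = 0, kept = 0;
  const double eps = 1e-9;
  for (int it = 0; it < dememorisation + steps; ++it) {
    int p = (int)std::floor(R::unif_rand() * 2 * N);
    int q = (int)std::floor(R::unif_rand() * 2 * N);
    if (p != q && a[p] != a[q] && (p / 2) != (q / 2)) {
      int ip = p / 2, iq = q / 2;
      int old1 = cell(a[2 * ip], a[2 * ip + 1]);
      int old2 = cell(a[2 * iq], a[2 * iq + 1]);
      std::swap(a[p], a[q]);
      int new1 = cell(a[2 * ip], a[2 * ip + 1]);
      int new2 = cell(a[2 * iq], a[2 * iq + 1]);
      // incremental log-probability update: remove old cells, add new;
      // a cell with count c contributes c*[het]*ln2 - ln(c!)
      auto contrib = [&](int cl) {
        int c = g[cl];
        return ((cl / k) != (cl % k) ? c * M_LN2 : 0.0) - R::lgammafn(c + 1.0);
      };
      lp_cur -= contrib(old1); g[old1]--; lp_cur += contrib(old1);
      lp_cur -= contrib(old2); g[old2]--; lp_cur += contrib(old2);
      lp_cur -= contrib(new1); g[new1]++; lp_cur += contrib(new1);
      lp_cur -= contrib(new2); g[new2]++; lp_cur += contrib(new2);
    }
    if ((it & 0x3FFF) == 0) lp_cur = tab_logprob(g, k); // limit float drift
    if (it >= dememorisation) {
      ++kept;
      if (lp_cur <= lp_obs + eps) ++hits;
    }
  }
  return (double)hits / (double)kept;
}
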