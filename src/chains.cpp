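#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Markov-chain exact tests for genotype data with fixed allele margins.
//
// Both chains operate on individual-level allele configurations and propose
// swapping one allele between two randomly chosen individuals.  The proposal
// is symmetric over configurations and the conditional null law is uniform
// over configurations, so the Metropolis conditional-probability ratio is
// identically one and every proposal is accepted; the induced stationary
// distribution over count tables is exactly the conditional (Levene /
// Fisher) null.  The p-value is the fraction of post-burn-in states whose
// conditional log-probability does not exceed the observed one (ties count
// as extreme).

static inline double urand() { return unif_rand(); }

// log conditional probability of a genotype count table, up to an additive
// constant: H*log(2) - sum(lgamma(n_ab + 1))
// [[Rcpp::export]]
double cpp_hwe_table_logprob(IntegerMatrix counts) {
  int k = counts.nrow();
  double lp = 0.0;
  for (int a = 0; a < k; ++a)
    for (int b = a; b < k; ++b) {
      lp -= lgamma((double)counts(a, b) + 1.0);
      // heterozygote factor: one log(2) per heterozygous individual
      if (a != b) lp += (double)counts(a, b) * M_LN2;
    }
  return lp;
}

// Chain for the female Hardy-Weinberg exact test (Guo-Thompson style).
// a1, a2: 0-based allele indices per diploid individual.
// [[Rcpp::export]]
List cpp_hwe_chain(IntegerVector a1, IntegerVector a2, int k,
                   double steps, double burnin) {
  int n = a1.size();
  std::vector<int> A1(a1.begin(), a1.end()), A2(a2.begin(), a2.end());
  std::vector<double> cnt((size_t)k * k, 0.0);
  double logpi = 0.0;

  auto idx = [k](int a, int b) {
    int lo = a < b ? a : b, hi = a < b ? b : a;
    return (size_t)lo * k + hi;
  };
  // build counts and initial log-probability
  for (int i = 0; i < n; ++i) cnt[idx(A1[i], A2[i])] += 1.0;
  for (int a = 0; a < k; ++a)
    for (int b = a; b < k; ++b) {
      double m = cnt[(size_t)a * k + b];
      logpi -= lgamma(m + 1.0);
      if (a != b) logpi += m * M_LN2;
    }
  const double logpi_obs = logpi, tol = 1e-9;

  auto rem = [&](int a, int b) {
    size_t c = idx(a, b);
    logpi += std::log(cnt[c]);
    cnt[c] -= 1.0;
    if (a != b) logpi -= M_LN2;
  };
  auto add = [&](int a, int b) {
    size_t c = idx(a, b);
    cnt[c] += 1.0;
    logpi -= std::log(cnt[c]);
    if (a != b) logpi += M_LN2;
  };

  double hits = 0.0, draws = 0.0;
  double total = steps;
  for (double s = 0; s < total; ++s) {
    int u = (int)(urand() * n); if (u == n) u = n - 1;
    int v = (int)(urand() * (n - 1)); if (v == n - 1) v = n - 2;
    if (v >= u) ++v;
    bool su = urand() < 0.5, sv = urand() < 0.5;
    int x = su ? A2[u] : A1[u];
    int y = sv ? A2[v] : A1[v];
    if (x != y) {
      rem(A1[u], A2[u]);
      rem(A1[v], A2[v]);
      if (su) A2[u] = y; else A1[u] = y;
      if (sv) A2[v] = x; else A1[v] = x;
      add(A1[u], A2[u]);
      add(A1[v], A2[v]);
    }
    if (s >= burnin) {
      draws += 1.0;
      if (logpi <= logpi_obs + tol) hits += 1.0;
    }
  }
  return List::create(_["p"] = hits / draws, _["draws"] = draws,
                      _["logp_obs"] = logpi_obs);
}

// Chain for the male (haploid) two-locus exact test of linkage
// disequilibrium: contingency table with fixed row/column margins.
// a, b: 0-based allele indices at the two loci per male.
// [[Rcpp::export]]
List cpp_haploid_chain(IntegerVector a, IntegerVector b, int ka, int kb,
                       double steps, double burnin) {
  int n = a.size();
  std::vector<int> B(b.begin(), b.end());
  std::vector<double> cnt((size_t)ka * kb, 0.0);
  double logpi = 0.0;
  for (int i = 0; i < n; ++i) cnt[(size_t)a[i] * kb + B[i]] += 1.0;
  for (size_t c = 0; c < cnt.size(); ++c) logpi -= lgamma(cnt[c] + 1.0);
  const double logpi_obs = logpi, tol = 1e-9;

  double hits = 0.0, draws = 0.0;
  for (double s = 0; s < steps; ++s) {
    int u = (int)(urand() * n); if (u == n) u = n - 1;
    int v = (int)(urand() * (n - 1)); if (v == n - 1) v = n - 2;
    if (v >= u) ++v;
    if (B[u] != B[v]) {
      size_t cu = (size_t)a[u] * kb + B[u], cv = (size_t)a[v] * kb + B[v];
      logpi += std::log(cnt[cu]) + std::log(cnt[cv]);
      cnt[cu] -= 1.0; cnt[cv] -= 1.0;
      int tmp = B[u]; B[u] = B[v]; B[v] = tmp;
      size_t nu = (size_t)a[u] * kb + B[u], nv = (size_t)a[v] * kb + B[v];
      cnt[nu] += 1.0; cnt[nv] += 1.0;
      logpi -= std::log(cnt[nu]) + std::log(cnt[nv]);
    }
    if (s >= burnin) {
      draws += 1.0;
      if (logpi <= logpi_obs + tol) hits += 1.0;
    }
  }
  return List::create(_["p"] = hits / draws, _["draws"] = draws,
                      _["logp_obs"] = logpi_obs);
}
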