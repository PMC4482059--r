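// Per-locus Gibbs sampler over allelic compositions.
//
// The composition universe is fixed and tiny (10 normal / 14 tumour states),
// so each full conditional is an explicit normalised vector.  Per-sample
// log-likelihoods for every candidate composition are computed once per
// locus (they do not depend on the other samples' states) and reused across
// sweeps; only the Dirichlet-multinomial prior term changes between sweeps.
//
// Uses R's RNG (seeded from the R side per locus) so that runs are
// reproducible and the chain trajectory can be replayed step-by-step by the
// pure-R reference sweep in the test suite: draws are inverse-CDF on the
// unnormalised conditional, consuming exactly one uniform per draw.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Canonical composition order: singletons, pairs, triples; lexicographic in
// A<C<G<T within each block.  Members are 0-based allele indices.
static const int NC_T = 14, NC_N = 10;
static const int COMP_SIZE[NC_T] = {1,1,1,1, 2,2,2,2,2,2, 3,3,3,3};
static const int COMP_MEM[NC_T][3] = {
  {0,-1,-1},{1,-1,-1},{2,-1,-1},{3,-1,-1},
  {0,1,-1},{0,2,-1},{0,3,-1},{1,2,-1},{1,3,-1},{2,3,-1},
  {0,1,2},{0,1,3},{0,2,3},{1,2,3}};

static bool comp_contains(int z, int allele) {
  for (int j = 0; j < COMP_SIZE[z]; ++j)
    if (COMP_MEM[z][j] == allele) return true;
  return false;
}

// MAP allele fractions for composition z given counts v and strength a,
// then log-likelihood over the reads (full per-read error model).
static double comp_loglik(int z, const int v[4], double a,
                          const IntegerVector& allele,
                          const NumericVector& err) {
  double f[4] = {0, 0, 0, 0};
  int M = COMP_SIZE[z];
  if (M == 1) {
    f[COMP_MEM[z][0]] = 1.0;
  } else {
    double denom = -M;
    for (int j = 0; j < M; ++j) denom += v[COMP_MEM[z][j]] + a;
    for (int j = 0; j < M; ++j) {
      int t = COMP_MEM[z][j];
      f[t] = (v[t] + a - 1.0) / denom;
    }
  }
  double ll = 0.0;
  int n = allele.size();
  for (int j = 0; j < n; ++j) {
    double ft = f[allele[j] - 1];
    double e = err[j];
    ll += std::log((1.0 - e) * ft + (e / 3.0) * (1.0 - ft));
  }
  return ll;
}

// Inverse-CDF draw from unnormalised weights p[0..n)
static int draw_from(const double* p, int n, double total) {
  double u = unif_rand() * total, cum = 0.0;
  for (int i = 0; i < n; ++i) {
    cum += p[i];
    if (u <= cum) return i;
  }
  return n - 1;
}

// [[Rcpp::export]]
List run_locus_chain_cpp(List alleles, List errors, int ref,
                         NumericVector a_strengths, double mu, double w,
                         double alpha, double beta, double gamma_,
                         double delta, int burn_in, int window,
                         int max_cycles, double mode_thresh, bool record) {
  const int n_samples = alleles.size();   // normal first
  const int n_tum = n_samples - 1;
  const int ref0 = ref - 1;

  // cached log-likelihoods: normal over 10 states, tumours over 14
  std::vector< std::vector<double> > ll(n_samples);
  for (int k = 0; k < n_samples; ++k) {
    IntegerVector a = alleles[k];
    NumericVector e = errors[k];
    int v[4] = {0, 0, 0, 0};
    for (int j = 0; j < a.size(); ++j) v[a[j] - 1]++;
    int nc = (k == 0) ? NC_N : NC_T;
    ll[k].resize(nc);
    for (int z = 0; z < nc; ++z)
      ll[k][z] = comp_loglik(z, v, a_strengths[k], a, e);
  }

  // normal pseudocounts (by relation to the reference base)
  double dN[NC_N];
  for (int z = 0; z < NC_N; ++z) {
    if (COMP_SIZE[z] == 1)
      dN[z] = w * (COMP_MEM[z][0] == ref0 ? delta : gamma_);
    else
      dN[z] = w * (comp_contains(z, ref0) ? alpha : beta);
  }
  // tumour pseudocounts for each possible normal state
  double dT[NC_N][NC_T];
  for (int sn = 0; sn < NC_N; ++sn) {
    double rest = 0.0;
    for (int z = 0; z < NC_T; ++z) {
      if (z == sn) continue;
      bool one_extra = false;
      if (COMP_SIZE[z] == COMP_SIZE[sn] + 1) {
        one_extra = true;
        for (int j = 0; j < COMP_SIZE[sn]; ++j)
          if (!comp_contains(z, COMP_MEM[sn][j])) { one_extra = false; break; }
      }
      dT[sn][z] = one_extra ? w * mu : w * mu * mu;
      rest += dT[sn][z];
    }
    dT[sn][sn] = w - rest;
  }

  // random initial state, uniform over each sample's universe
  int sN = (int)(unif_rand() * NC_N);
  if (sN >= NC_N) sN = NC_N - 1;
  std::vector<int> sT(n_tum);
  for (int i = 0; i < n_tum; ++i) {
    sT[i] = (int)(unif_rand() * NC_T);
    if (sT[i] >= NC_T) sT[i] = NC_T - 1;
  }

  std::vector< std::vector<int> > tally(n_samples,
                                        std::vector<int>(NC_T, 0));
  std::vector< std::vector<int> > wtally(n_samples,
                                         std::vector<int>(NC_T, 0));
  std::vector<int> prev_modes(n_samples, -1);
  bool prev_ok = false, have_prev = false, converged = false;

  IntegerMatrix traj = record ? IntegerMatrix(max_cycles, n_samples)
                              : IntegerMatrix(0, 0);

  double logp[NC_T], p[NC_T];
  int sweeps = 0;
  while (sweeps < max_cycles) {
    // --- normal draw
    {
      int n_counts[NC_N] = {0,0,0,0,0,0,0,0,0,0};
      for (int i = 0; i < n_tum; ++i)
        if (sT[i] < NC_N) n_counts[sT[i]]++;
      double m = R_NegInf;
      for (int z = 0; z < NC_N; ++z) {
        logp[z] = ll[0][z] + std::log(n_counts[z] + dN[z]);
        if (logp[z] > m) m = logp[z];
      }
      double tot = 0.0;
      for (int z = 0; z < NC_N; ++z) { p[z] = std::exp(logp[z] - m); tot += p[z]; }
      sN = draw_from(p, NC_N, tot);
    }
    // --- tumour draws, input order
    for (int i = 0; i < n_tum; ++i) {
      int c_counts[NC_T] = {0,0,0,0,0,0,0,0,0,0,0,0,0,0};
      for (int j = 0; j < n_tum; ++j)
        if (j != i) c_counts[sT[j]]++;
      double m = R_NegInf;
      for (int z = 0; z < NC_T; ++z) {
        logp[z] = ll[i + 1][z] + std::log(c_counts[z] + dT[sN][z]);
        if (logp[z] > m) m = logp[z];
      }
      double tot = 0.0;
      for (int z = 0; z < NC_T; ++z) { p[z] = std::exp(logp[z] - m); tot += p[z]; }
      sT[i] = draw_from(p, NC_T, tot);
    }

    if (record) {
      traj(sweeps, 0) = sN + 1;
      for (int i = 0; i < n_tum; ++i) traj(sweeps, i + 1) = sT[i] + 1;
    }
    ++sweeps;

    if (sweeps > burn_in) {
      tally[0][sN]++; wtally[0][sN]++;
      for (int i = 0; i < n_tum; ++i) {
        tally[i + 1][sT[i]]++;
        wtally[i + 1][sT[i]]++;
      }
      int post = sweeps - burn_in;
      if (!record && post % window == 0) {
        // windowed convergence check: identical modes across the two most
        // recent windows, each with modal frequency >= threshold
        std::vector<int> modes(n_samples);
        bool ok = true;
        for (int k = 0; k < n_samples; ++k) {
          int best = 0;
          for (int z = 1; z < NC_T; ++z)
            if (wtally[k][z] > wtally[k][best]) best = z;
          modes[k] = best;
          if ((double)wtally[k][best] / window < mode_thresh) ok = false;
          for (int z = 0; z < NC_T; ++z) wtally[k][z] = 0;
        }
        if (have_prev && ok && prev_ok) {
          bool same = true;
          for (int k = 0; k < n_samples; ++k)
            if (modes[k] != prev_modes[k]) { same = false; break; }
          if (same) converged = true;
        }
        prev_modes = modes; prev_ok = ok; have_prev = true;
        if (converged) break;
      }
    }
  }

  IntegerMatrix tallies(n_samples, NC_T);
  IntegerVector modes(n_samples);
  NumericVector mode_freq(n_samples);
  int post = sweeps - burn_in;
  for (int k = 0; k < n_samples; ++k) {
    int best = 0;
    for (int z = 0; z < NC_T; ++z) {
      tallies(k, z) = tally[k][z];
      if (tally[k][z] > tally[k][best]) best = z;
    }
    modes[k] = best + 1;
    mode_freq[k] = post > 0 ? (double)tally[k][best] / post : NA_REAL;
  }

  List out = List::create(_["tallies"] = tallies, _["modes"] = modes,
                          _["mode_freq"] = mode_freq,
                          _["sweeps_run"] = sweeps,
                          _["converged"] = converged);
  if (record) out["trajectory"] = traj(Range(0, sweeps - 1),
                                       Range(0, n_samples - 1));
  return out;
}
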