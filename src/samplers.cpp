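// Monte Carlo inner loops: 2D Ising samplers (Swendsen-Wang cluster updates,
// Metropolis single-site sweeps), block-Gibbs sampling for binary RBMs, and
// Monte Carlo estimation of conditional codeword energies. All samplers take
// an explicit integer seed and draw from a private mt19937_64 stream, so
// results are reproducible and independent of R's RNG state.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline double softplus(double x) {
  if (x > 30.0) return x;
  if (x < -30.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double sigmoid(double x) {
  if (x >= 0) {
    return 1.0 / (1.0 + std::exp(-x));
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

// ---------------------------------------------------------------------------
// Ising lattice, periodic boundaries, J = 1, k_B = 1, spins sigma in {-1,+1}.
// Energy E = -sum_<ij> sigma_i sigma_j over nearest-neighbour pairs.

struct UnionFind {
  std::vector<int> parent;
  UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int i) {
    while (parent[i] != i) {
      parent[i] = parent[parent[i]];
      i = parent[i];
    }
    return i;
  }
  void unite(int a, int b) {
    int ra = find(a), rb = find(b);
    if (ra != rb) parent[ra] = rb;
  }
};

// One Swendsen-Wang update: bond activation between aligned neighbours with
// probability 1 - exp(-2/T), cluster identification, independent cluster flips.
static void sw_step(std::vector<int8_t>& s, int L, double p_bond,
                    std::mt19937_64& rng, std::uniform_real_distribution<double>& unif) {
  const int n = L * L;
  UnionFind uf(n);
  for (int y = 0; y < L; ++y) {
    for (int x = 0; x < L; ++x) {
      int i = y * L + x;
      int right = y * L + (x + 1) % L;
      int down = ((y + 1) % L) * L + x;
      if (s[i] == s[right] && unif(rng) < p_bond) uf.unite(i, right);
      if (s[i] == s[down] && unif(rng) < p_bond) uf.unite(i, down);
    }
  }
  // one fair-coin flip decision per cluster root
  std::vector<int8_t> flip(n, 0);
  std::vector<int8_t> decided(n, 0);
  for (int i = 0; i < n; ++i) {
    int r = uf.find(i);
    if (!decided[r]) {
      decided[r] = 1;
      flip[r] = (unif(rng) < 0.5) ? 1 : 0;
    }
    if (flip[r]) s[i] = -s[i];
  }
}

// One Metropolis sweep = L^2 random single-site proposals.
static void metropolis_sweep(std::vector<int8_t>& s, int L, double T,
                             std::mt19937_64& rng,
                             std::uniform_real_distribution<double>& unif) {
  const int n = L * L;
  std::uniform_int_distribution<int> pick(0, n - 1);
  for (int k = 0; k < n; ++k) {
    int i = pick(rng);
    int y = i / L, x = i % L;
    int nb = s[y * L + (x + 1) % L] + s[y * L + (x + L - 1) % L] +
             s[((y + 1) % L) * L + x] + s[((y + L - 1) % L) * L + x];
    double dE = 2.0 * s[i] * nb;
    if (dE <= 0.0 || unif(rng) < std::exp(-dE / T)) s[i] = -s[i];
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_sample_ising(int L, double T, int n_samples, int burn_in,
                               int thin, int seed, std::string method) {
  const int n = L * L;
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<int8_t> s(n);
  for (int i = 0; i < n; ++i) s[i] = (unif(rng) < 0.5) ? 1 : -1;

  bool sw = (method == "swendsen-wang");
  double p_bond = 1.0 - std::exp(-2.0 / T);

  IntegerMatrix out(n_samples, n);  // 0/1 bits, s = (sigma + 1) / 2
  for (int b = 0; b < burn_in; ++b) {
    if (sw) sw_step(s, L, p_bond, rng, unif);
    else metropolis_sweep(s, L, T, rng, unif);
  }
  for (int k = 0; k < n_samples; ++k) {
    for (int t = 0; t < thin; ++t) {
      if (sw) sw_step(s, L, p_bond, rng, unif);
      else metropolis_sweep(s, L, T, rng, unif);
    }
    for (int i = 0; i < n; ++i) out(k, i) = (s[i] + 1) / 2;
  }
  return out;
}

// ---------------------------------------------------------------------------
// RBM block Gibbs: one step = update all hidden given visible, then all
// visible given hidden. W is (N_h x N_v); parameters are assumed already
// scaled by the inverse temperature.

// [[Rcpp::export]]
List cpp_rbm_gibbs(NumericMatrix W, NumericVector bh, NumericVector bv,
                   int n_chains, int keep_per_chain, int thin, int burn_in,
                   int seed) {
  const int Nh = W.nrow(), Nv = W.ncol();
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  const int n_keep = n_chains * keep_per_chain;
  IntegerMatrix H(n_keep, Nh), V(n_keep, Nv);
  std::vector<int8_t> h(Nh), v(Nv);
  int row = 0;
  for (int c = 0; c < n_chains; ++c) {
    for (int i = 0; i < Nv; ++i) v[i] = (unif(rng) < 0.5) ? 1 : 0;
    for (int j = 0; j < Nh; ++j) h[j] = (unif(rng) < 0.5) ? 1 : 0;
    int total = burn_in + keep_per_chain * thin;
    for (int t = 1; t <= total; ++t) {
      for (int j = 0; j < Nh; ++j) {
        double a = bh[j];
        for (int i = 0; i < Nv; ++i) if (v[i]) a += W(j, i);
        h[j] = (unif(rng) < sigmoid(a)) ? 1 : 0;
      }
      for (int i = 0; i < Nv; ++i) {
        double a = bv[i];
        for (int j = 0; j < Nh; ++j) if (h[j]) a += W(j, i);
        v[i] = (unif(rng) < sigmoid(a)) ? 1 : 0;
      }
      if (t > burn_in && (t - burn_in) % thin == 0) {
        for (int j = 0; j < Nh; ++j) H(row, j) = h[j];
        for (int i = 0; i < Nv; ++i) V(row, i) = v[i];
        ++row;
      }
    }
  }
  return List::create(_["h"] = H, _["v"] = V);
}

// ---------------------------------------------------------------------------
// Monte Carlo estimate of the expected codeword (hidden-marginal) energy
// <E_h>_{h|v} for each stimulus. probs is (n_stim x N_h): the factorial
// conditional P(h_j = 1 | v). E_h = -bh.h - sum_i softplus((W^T h)_i + bv_i),
// in nats, unnormalized. Also returns the minimum single-sample energy seen
// (anchor candidate for normalization).

// [[Rcpp::export]]
List cpp_expected_hidden_energy(NumericMatrix W, NumericVector bh,
                                NumericVector bv, NumericMatrix probs,
                                int n_samples, int seed) {
  const int Nh = W.nrow(), Nv = W.ncol();
  const int n_stim = probs.nrow();
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  NumericVector mean_energy(n_stim);
  double min_energy = R_PosInf;
  std::vector<int8_t> h(Nh);
  std::vector<double> a(Nv);
  for (int sidx = 0; sidx < n_stim; ++sidx) {
    double acc = 0.0;
    for (int rep = 0; rep < n_samples; ++rep) {
      double e = 0.0;
      for (int j = 0; j < Nh; ++j) {
        h[j] = (unif(rng) < probs(sidx, j)) ? 1 : 0;
        if (h[j]) e -= bh[j];
      }
      for (int i = 0; i < Nv; ++i) a[i] = bv[i];
      for (int j = 0; j < Nh; ++j) {
        if (h[j]) for (int i = 0; i < Nv; ++i) a[i] += W(j, i);
      }
      for (int i = 0; i < Nv; ++i) e -= softplus(a[i]);
      acc += e;
      if (e < min_energy) min_energy = e;
    }
    mean_energy[sidx] = acc / n_samples;
  }
  return List::create(_["mean_energy"] = mean_energy,
                      _["min_energy"] = min_energy);
}
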