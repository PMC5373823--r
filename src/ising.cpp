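#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// xoshiro256++ with splitmix64 seeding: one counter-based stream per run,
// reproducible from a single integer seed independent of R's RNG.
namespace {

struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline int below(int n) { return (int)(unif() * n); }  // 0..n-1
};

inline int wrap(int a, int L) { return a < 0 ? a + L : (a >= L ? a - L : a); }

}  // namespace

// Total energy: H = -sum_<ij> S_i S_j  - field term. Bonds counted once.
// field_type: 0 none, 1 receptor field (couples to receptor occupancy),
// 2 domain field (couples to all spins).
// [[Rcpp::export]]
double ising_energy_cpp(IntegerMatrix spin, IntegerMatrix species,
                        NumericMatrix field, int field_type) {
  const int L = spin.nrow();
  double H = 0.0;
  for (int i = 0; i < L; ++i) {
    for (int j = 0; j < L; ++j) {
      const int s = spin(i, j);
      H -= s * (spin(wrap(i + 1, L), j) + spin(i, wrap(j + 1, L)));
      if (field_type == 1) {
        if (species(i, j) == 1) H -= field(i, j);
      } else if (field_type == 2) {
        H -= s * field(i, j);
      }
    }
  }
  return H;
}

// Conserved order-parameter (spin exchange) simulator with species and
// phosphorylation reactions. Species codes: 0 background, 1 receptor,
// 2 kinase, 3 phosphatase. Spins and species move together in an exchange.
//
// Reactions fire only on accepted exchanges that change the state, and are
// evaluated for the two exchanged sites and their 4-neighborhoods: a
// receptor with a kinase neighbor is phosphorylated with p_phos per
// adjacency; with rbk enabled a phosphorylated receptor neighbor
// phosphorylates with p_rbk; a phosphatase neighbor dephosphorylates with
// p_dephos, drawn last so phosphatase contact dominates within one update.
// [[Rcpp::export]]
List ising_run_cpp(IntegerMatrix spin0, IntegerMatrix species0,
                   LogicalVector phospho0, double beta,
                   NumericMatrix field, int field_type,
                   double p_phos, double p_dephos, double p_rbk,
                   bool rbk_enabled, bool reactions,
                   int sweeps, bool local_moves,
                   int record_every, int snapshot_every,
                   double seed) {
  const int L = spin0.nrow();
  const int N = L * L;
  std::vector<int8_t> spin(N), species(N), phos(N);
  std::vector<double> phi(N);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) {
      spin[i + L * j] = (int8_t)spin0(i, j);
      species[i + L * j] = (int8_t)species0(i, j);
      phos[i + L * j] = (int8_t)(phospho0[i + L * j] ? 1 : 0);
      phi[i + L * j] = field(i, j);
    }
  Rng rng((uint64_t)seed);

  int n_receptors = 0;
  for (int k = 0; k < N; ++k) if (species[k] == 1) ++n_receptors;

  const int proposals_per_sweep = 2 * N;
  std::vector<double> trace_py, trace_energy;
  List snapshots;
  std::vector<int> snap_sweeps;

  auto nb = [&](int k, int d) -> int {
    const int i = k % L, j = k / L;
    switch (d) {
      case 0: return wrap(i + 1, L) + L * j;
      case 1: return wrap(i - 1, L) + L * j;
      case 2: return i + L * wrap(j + 1, L);
      default: return i + L * wrap(j - 1, L);
    }
  };

  auto react_site = [&](int s) {
    if (species[s] != 1) return;
    // kinase / RBK draws first, phosphatase last
    for (int d = 0; d < 4; ++d) {
      const int q = nb(s, d);
      if (species[q] == 2 && !phos[s] && rng.unif() < p_phos) phos[s] = 1;
    }
    if (rbk_enabled) {
      for (int d = 0; d < 4; ++d) {
        const int q = nb(s, d);
        if (species[q] == 1 && phos[q] && !phos[s] && rng.unif() < p_rbk)
          phos[s] = 1;
      }
    }
    for (int d = 0; d < 4; ++d) {
      const int q = nb(s, d);
      if (species[q] == 3 && phos[s] && rng.unif() < p_dephos) phos[s] = 0;
    }
  };

  double energy = 0.0;
  bool track_energy = record_every > 0;
  if (track_energy) {
    // recompute via the exported kernel logic
    for (int j = 0; j < L; ++j)
      for (int i = 0; i < L; ++i) {
        const int k = i + L * j;
        energy -= spin[k] * (spin[nb(k, 0)] + spin[nb(k, 2)]);
        if (field_type == 1) { if (species[k] == 1) energy -= phi[k]; }
        else if (field_type == 2) energy -= spin[k] * phi[k];
      }
  }

  long long accepted = 0;
  for (int sw = 1; sw <= sweeps; ++sw) {
    for (int p = 0; p < proposals_per_sweep; ++p) {
      int a, b;
      if (local_moves) {
        a = rng.below(N);
        b = nb(a, rng.below(4));
      } else {
        a = rng.below(N);
        do { b = rng.below(N); } while (b == a);
      }
      const int sa = spin[a], sb = spin[b];
      const int8_t pa = species[a], pb = species[b];
      const bool same = (sa == sb) && (pa == pb) && (phos[a] == phos[b]);
      if (same) { ++accepted; continue; }  // dH = 0, no state change

      // neighbor spin sums excluding the partner site
      int ma = 0, mb = 0;
      bool adjacent = false;
      for (int d = 0; d < 4; ++d) {
        const int q = nb(a, d);
        if (q == b) { adjacent = true; continue; }
        ma += spin[q];
      }
      for (int d = 0; d < 4; ++d) {
        const int q = nb(b, d);
        if (q == a) continue;
        mb += spin[q];
      }
      (void)adjacent;
      // bonds: before -(sa*ma + sb*mb), after -(sb*ma + sa*mb); the a-b
      // bond itself (when adjacent) is unchanged by the exchange
      double dH = (double)(sa - sb) * (double)(ma - mb);
      if (field_type == 1) {
        const double fa = phi[a], fb = phi[b];
        const double before = -((pa == 1) ? fa : 0.0) - ((pb == 1) ? fb : 0.0);
        const double after  = -((pb == 1) ? fa : 0.0) - ((pa == 1) ? fb : 0.0);
        dH += after - before;
      } else if (field_type == 2) {
        dH += (double)(sa - sb) * (phi[a] - phi[b]);
      }
      bool accept = dH <= 0.0 || rng.unif() < std::exp(-beta * dH);
      if (!accept) continue;
      ++accepted;
      std::swap(spin[a], spin[b]);
      std::swap(species[a], species[b]);
      std::swap(phos[a], phos[b]);
      if (track_energy) energy += dH;
      if (reactions) {
        react_site(a); react_site(b);
        for (int d = 0; d < 4; ++d) react_site(nb(a, d));
        for (int d = 0; d < 4; ++d) react_site(nb(b, d));
      }
    }
    if (record_every > 0 && sw % record_every == 0) {
      int np = 0;
      for (int k = 0; k < N; ++k) if (phos[k]) ++np;
      trace_py.push_back(n_receptors ? (double)np / n_receptors : 0.0);
      trace_energy.push_back(energy);
    }
    if (snapshot_every > 0 && sw % snapshot_every == 0) {
      IntegerMatrix sp(L, L), sc(L, L), ph(L, L);
      for (int j = 0; j < L; ++j)
        for (int i = 0; i < L; ++i) {
          sp(i, j) = spin[i + L * j];
          sc(i, j) = species[i + L * j];
          ph(i, j) = phos[i + L * j];
        }
      snapshots.push_back(List::create(_["sweep"] = sw, _["spin"] = sp,
                                       _["species"] = sc, _["phospho"] = ph));
      snap_sweeps.push_back(sw);
    }
  }

  IntegerMatrix spin_out(L, L), species_out(L, L);
  LogicalVector phos_out(N);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) {
      spin_out(i, j) = spin[i + L * j];
      species_out(i, j) = species[i + L * j];
      phos_out[i + L * j] = phos[i + L * j] != 0;
    }
  return List::create(
    _["spin"] = spin_out, _["species"] = species_out,
    _["phospho"] = phos_out,
    _["trace_py"] = NumericVector(trace_py.begin(), trace_py.end()),
    _["trace_energy"] = NumericVector(trace_energy.begin(), trace_energy.end()),
    _["snapshots"] = snapshots, _["accepted"] = (double)accepted);
}

// Non-conserved single-spin-flip Metropolis sampler used only to locate
// the critical temperature by Binder cumulant crossing. Returns <|m|^2>,
// <|m|^4> and the cumulant U = 1 - <m^4>/(3 <m^2>^2).
// [[Rcpp::export]]
NumericVector ising_binder_cpp(int L, double temperature, int equil_sweeps,
                               int meas_sweeps, int thin, double seed) {
  const int N = L * L;
  const double beta = 1.0 / temperature;
  Rng rng((uint64_t)seed);
  std::vector<int8_t> spin(N);
  for (int k = 0; k < N; ++k) spin[k] = rng.unif() < 0.5 ? -1 : 1;
  long long M = 0;
  for (int k = 0; k < N; ++k) M += spin[k];
  // acceptance lookup for dH in {4, 8} (units of J, dH = 2*s*m)
  double acc[9];
  for (int d = 0; d <= 8; ++d) acc[d] = std::exp(-beta * d);
  double sum2 = 0.0, sum4 = 0.0;
  long long nsamp = 0;
  const int total = equil_sweeps + meas_sweeps;
  for (int sw = 1; sw <= total; ++sw) {
    for (int p = 0; p < N; ++p) {
      const int k = rng.below(N);
      const int i = k % L, j = k / L;
      const int m = spin[wrap(i + 1, L) + L * j] + spin[wrap(i - 1, L) + L * j]
                  + spin[i + L * wrap(j + 1, L)] + spin[i + L * wrap(j - 1, L)];
      const int dH = 2 * spin[k] * m;
      if (dH <= 0 || rng.unif() < acc[dH]) {
        M -= 2 * spin[k];
        spin[k] = -spin[k];
      }
    }
    if (sw > equil_sweeps && (sw - equil_sweeps) % thin == 0) {
      const double m1 = (double)M / N;
      const double m2 = m1 * m1;
      sum2 += m2; sum4 += m2 * m2;
      ++nsamp;
    }
  }
  const double m2 = sum2 / nsamp, m4 = sum4 / nsamp;
  return NumericVector::create(m2, m4, 1.0 - m4 / (3.0 * m2 * m2));
}
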