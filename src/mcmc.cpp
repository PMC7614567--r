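#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Deterministic, platform-independent RNG: splitmix64 seeding + xoshiro256++.
namespace {

inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform integer in [0, n)
  inline int unif_int(int n) { return (int)(unif() * n); }
};

// chain-specific seed stream derived from one master seed
inline uint64_t chain_seed(uint64_t master, int chain) {
  uint64_t x = master;
  uint64_t out = splitmix64(x);
  for (int i = 0; i <= chain; ++i) out = splitmix64(x);
  return out;
}

// E(s) = -sum_i h_i(s_i) - sum_{i<j} J_ij(s_i, s_j); states 0-based here
inline double full_energy(const NumericMatrix &h, const NumericMatrix &J,
                          const IntegerVector &s, int q) {
  const int L = s.size();
  double e = 0.0;
  for (int i = 0; i < L; ++i) {
    e -= h(i, s[i]);
    const int oi = i * q + s[i];
    for (int j = i + 1; j < L; ++j) e -= J(oi, j * q + s[j]);
  }
  return e;
}

} // namespace

// Plain Metropolis sampling of the Potts Boltzmann distribution at
// temperature T. One sweep = L single-site proposals (uniform site, uniform
// one of the q-1 other states). Returns recorded states, 0-based.
// [[Rcpp::export]]
IntegerMatrix cpp_run_chains(NumericMatrix h, NumericMatrix J, int q,
                             double temperature, IntegerMatrix init,
                             int n_sweeps, int record_every, double seed) {
  const int L = h.nrow();
  const int n_chains = init.nrow();
  const int n_rec = n_sweeps / record_every;
  IntegerMatrix out(n_chains * n_rec, L);
  const double invT = 1.0 / temperature;

  for (int c = 0; c < n_chains; ++c) {
    Xoshiro rng(chain_seed((uint64_t)seed, c));
    IntegerVector s(L);
    for (int i = 0; i < L; ++i) s[i] = init(c, i);
    double ecur = full_energy(h, J, s, q);
    int rec = 0;
    for (int sw = 1; sw <= n_sweeps; ++sw) {
      for (int step = 0; step < L; ++step) {
        const int i = rng.unif_int(L);
        int anew = rng.unif_int(q - 1);
        if (anew >= s[i]) ++anew;
        const int o_old = i * q + s[i];
        const int o_new = i * q + anew;
        double dE = -(h(i, anew) - h(i, s[i]));
        for (int j = 0; j < L; ++j) {
          if (j == i) continue;
          const int oj = j * q + s[j];
          dE -= J(o_new, oj) - J(o_old, oj);
        }
        if (dE <= 0.0 || rng.unif() < std::exp(-dE * invT)) {
          s[i] = anew;
          ecur += dE;
        }
      }
      if (sw % record_every == 0) {
        const int row = c * n_rec + rec;
        for (int i = 0; i < L; ++i) out(row, i) = s[i];
        ++rec;
      }
    }
    (void)ecur;
  }
  return out;
}

// Energy-cache consistency helper used by tests: recompute from scratch.
// [[Rcpp::export]]
double cpp_energy(NumericMatrix h, NumericMatrix J, IntegerVector s, int q) {
  return full_energy(h, J, s, q);
}

namespace {

struct GenState {
  IntegerVector s;        // current concatenated mutant (0-based states)
  std::vector<int> mutpos_a, mutpos_b; // currently mutated positions (0-based)
  double eiA, eiB, ecAB, exAB, exBA;   // energy components
};

// component deltas for setting position p (0-based, global) to state anew
struct Delta { double eiA, eiB, ecAB, exAB, exBA; };

inline Delta site_delta(const NumericMatrix &h, const NumericMatrix &J, int q,
                        int boundary, const IntegerVector &s,
                        const IntegerVector &wt, int p, int anew) {
  Delta d = {0, 0, 0, 0, 0};
  const int L = s.size();
  const int o_old = p * q + s[p];
  const int o_new = p * q + anew;
  const double dh = -(h(p, anew) - h(p, s[p]));
  if (p < boundary) {
    d.eiA = dh;
    for (int j = 0; j < boundary; ++j) {
      if (j == p) continue;
      const int oj = j * q + s[j];
      d.eiA -= J(o_new, oj) - J(o_old, oj);
    }
    for (int j = boundary; j < L; ++j) {
      const int oj = j * q + s[j];
      const int ow = j * q + wt[j];
      d.ecAB -= J(o_new, oj) - J(o_old, oj);
      d.exAB -= J(o_new, ow) - J(o_old, ow);
    }
  } else {
    d.eiB = dh;
    for (int j = boundary; j < L; ++j) {
      if (j == p) continue;
      const int oj = j * q + s[j];
      d.eiB -= J(o_new, oj) - J(o_old, oj);
    }
    for (int j = 0; j < boundary; ++j) {
      const int oj = j * q + s[j];
      const int ow = j * q + wt[j];
      d.ecAB -= J(o_new, oj) - J(o_old, oj);
      d.exBA -= J(o_new, ow) - J(o_old, ow);
    }
  }
  return d;
}

inline void apply_delta(GenState &st, const Delta &d) {
  st.eiA += d.eiA; st.eiB += d.eiB; st.ecAB += d.ecAB;
  st.exAB += d.exAB; st.exBA += d.exBA;
}

inline double loss_delta(const Delta &d, double invT, double invT2) {
  // loss = (E_intra(A*) + E_intra(B*) + E_inter(A*,B*)) / T
  //        - (E_inter(A*,B) + E_inter(A,B*)) / T2   (invT2 = 0: direct mode)
  return (d.eiA + d.eiB + d.ecAB) * invT - (d.exAB + d.exBA) * invT2;
}

} // namespace

// Constrained Metropolis-Hastings sampling of mutant pairs at exactly
// (k_a, k_b) mutations. allowed_states is an L x q logical matrix of legal
// *mutant* states per position (wild-type state always excluded). Move
// mixture per MC step: pick an eligible protein uniformly; with prob 1/2
// resample the state of one mutated position, else swap a mutated position
// back to wild type while mutating a currently-wild-type allowed position.
// Acceptance includes the Hastings factor m_new/m_old for swap moves so the
// stationary distribution on the constrained space is
//   p(s) propto exp(-[E_intra(A)+E_intra(B)+E_inter(A,B)]/T
//                 + [E_inter(A*,B)+E_inter(A,B*)]/T2).
// Returns recorded sequences (0-based) and their five delta scores.
// [[Rcpp::export]]
List cpp_generate(NumericMatrix h, NumericMatrix J, int q, int boundary,
                  IntegerVector wt, LogicalMatrix allowed_states,
                  IntegerVector allowed_pos_a, IntegerVector allowed_pos_b,
                  int k_a, int k_b, double temperature, double inv_t2,
                  int n_samples, int record_every, double seed) {
  const int L = wt.size();
  const double invT = 1.0 / temperature;
  Xoshiro rng(chain_seed((uint64_t)seed, 0));

  std::vector<int> m(L, 0); // number of legal mutant states per position
  for (int i = 0; i < L; ++i)
    for (int a = 0; a < q; ++a)
      if (allowed_states(i, a)) ++m[i];

  // initialization: random k mutations on random allowed positions
  GenState st;
  st.s = clone(wt);
  auto init_protein = [&](const IntegerVector &pos, int k,
                          std::vector<int> &mut) {
    std::vector<int> pool(pos.begin(), pos.end());
    for (int t = 0; t < k; ++t) {
      const int pick = rng.unif_int((int)pool.size());
      const int p = pool[pick];
      pool.erase(pool.begin() + pick);
      int r = rng.unif_int(m[p]);
      int anew = -1;
      for (int a = 0; a < q; ++a) {
        if (allowed_states(p, a) && r-- == 0) { anew = a; break; }
      }
      st.s[p] = anew;
      mut.push_back(p);
    }
  };
  init_protein(allowed_pos_a, k_a, st.mutpos_a);
  init_protein(allowed_pos_b, k_b, st.mutpos_b);

  // components from scratch (for the current state and the wild type)
  auto components = [&](const IntegerVector &s, double &eiA, double &eiB,
                        double &ecAB) {
    eiA = eiB = ecAB = 0.0;
    for (int i = 0; i < L; ++i) {
      if (i < boundary) eiA -= h(i, s[i]); else eiB -= h(i, s[i]);
      const int oi = i * q + s[i];
      for (int j = i + 1; j < L; ++j) {
        const double v = J(oi, j * q + s[j]);
        if (j < boundary) eiA -= v;
        else if (i >= boundary) eiB -= v;
        else ecAB -= v;
      }
    }
  };
  double wiA, wiB, wcAB;
  components(wt, wiA, wiB, wcAB);
  components(st.s, st.eiA, st.eiB, st.ecAB);
  st.exAB = st.exBA = 0.0;
  for (int i = 0; i < boundary; ++i) {
    const int oi = i * q + st.s[i];
    const int wi = i * q + wt[i];
    for (int j = boundary; j < L; ++j) {
      st.exAB -= J(oi, j * q + wt[j]);
      st.exBA -= J(wi, j * q + st.s[j]);
    }
  }

  IntegerMatrix seqs(n_samples, L);
  NumericMatrix scores(n_samples, 5);
  int rec = 0;
  const bool elig_a = k_a > 0, elig_b = k_b > 0;
  if (!elig_a && !elig_b) stop("both mutation counts are zero");

  long sweep = 0;
  while (rec < n_samples) {
    ++sweep;
    for (int step = 0; step < L; ++step) {
      // choose an eligible protein
      bool in_a;
      if (elig_a && elig_b) in_a = rng.unif() < 0.5;
      else in_a = elig_a;
      std::vector<int> &mut = in_a ? st.mutpos_a : st.mutpos_b;
      const IntegerVector &pos = in_a ? allowed_pos_a : allowed_pos_b;
      const int k = (int)mut.size();
      const int n_allowed = pos.size();

      if (rng.unif() < 0.5) {
        // resample the amino acid at one mutated position
        const int p = mut[rng.unif_int(k)];
        if (m[p] < 2) continue;
        int r = rng.unif_int(m[p] - 1);
        int anew = -1;
        for (int a = 0; a < q; ++a) {
          if (allowed_states(p, a) && a != st.s[p] && r-- == 0) {
            anew = a; break;
          }
        }
        Delta d = site_delta(h, J, q, boundary, st.s, wt, p, anew);
        const double dl = loss_delta(d, invT, inv_t2);
        if (dl <= 0.0 || rng.unif() < std::exp(-dl)) {
          st.s[p] = anew;
          apply_delta(st, d);
        }
      } else {
        // swap: revert one mutated position, mutate a wild-type position
        if (k >= n_allowed || k == 0) continue;
        const int mi = rng.unif_int(k);
        const int p = mut[mi];
        // draw a currently wild-type allowed position
        int pn;
        do { pn = pos[rng.unif_int(n_allowed)]; } while (st.s[pn] != wt[pn]);
        int r = rng.unif_int(m[pn]);
        int anew = -1;
        for (int a = 0; a < q; ++a) {
          if (allowed_states(pn, a) && r-- == 0) { anew = a; break; }
        }
        const int s_p_old = st.s[p];
        Delta d1 = site_delta(h, J, q, boundary, st.s, wt, p, wt[p]);
        st.s[p] = wt[p]; // tentatively apply to evaluate the second site
        Delta d2 = site_delta(h, J, q, boundary, st.s, wt, pn, anew);
        Delta d = {d1.eiA + d2.eiA, d1.eiB + d2.eiB, d1.ecAB + d2.ecAB,
                   d1.exAB + d2.exAB, d1.exBA + d2.exBA};
        const double dl = loss_delta(d, invT, inv_t2);
        const double hastings = (double)m[pn] / (double)m[p];
        if (rng.unif() < hastings * std::exp(-dl)) {
          st.s[pn] = anew;
          apply_delta(st, d);
          mut[mi] = pn;
        } else {
          st.s[p] = s_p_old; // revert tentative change
        }
      }
    }
    if (sweep % record_every == 0) {
      for (int i = 0; i < L; ++i) seqs(rec, i) = st.s[i];
      scores(rec, 0) = st.eiA - wiA;
      scores(rec, 1) = st.eiB - wiB;
      scores(rec, 2) = st.ecAB - wcAB;
      scores(rec, 3) = st.exAB - wcAB;
      scores(rec, 4) = st.exBA - wcAB;
      ++rec;
    }
  }
  return List::create(_["seqs"] = seqs, _["scores"] = scores);
}
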