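// Absorbing random-walk engine for the camper-travel network.
//
// The transition structure arrives in CSR form: for node k the outgoing
// entries live in [row_ptr[k], row_ptr[k+1]) of col_idx, with cum[q] the
// within-row cumulative transition probability. Row sums are < 1, so each
// step either moves (u below the row total) or terminates.
//
// RNG: self-contained xoshiro256++ seeded via splitmix64. Each origin gets
// its own substream derived from (base seed, origin id), so per-origin
// results do not depend on the order origins are processed in.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t& x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
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
  // uniform double in [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

static inline uint64_t stream_seed(double base_seed, int origin) {
  uint64_t b = (uint64_t)(int64_t)base_seed;
  uint64_t x = b ^ (0xD1B54A32D192ED03ULL * (uint64_t)(origin + 1));
  return splitmix64(x);
}

// One step from node k: returns next node index, or -1 on terminal draw,
// or -2 when the node has no outgoing entries.
static inline int step_from(int k, const int* row_ptr, const int* col_idx,
                            const double* cum, Xoshiro256pp& rng) {
  int lo = row_ptr[k], hi = row_ptr[k + 1];
  if (lo == hi) return -2;
  double u = rng.unif();
  if (u >= cum[hi - 1]) return -1;
  // binary search: first q in [lo, hi) with u < cum[q]
  while (lo < hi) {
    int mid = lo + ((hi - lo) >> 1);
    if (u < cum[mid]) hi = mid; else lo = mid + 1;
  }
  return col_idx[lo];
}

// Simulate n_sims walks from one origin; count, per node, the number of
// walks that visit it at least once (the origin itself is never counted).
// [[Rcpp::export]]
List cpp_walk_counts(IntegerVector row_ptr, IntegerVector col_idx,
                     NumericVector cum, int n_nodes, int origin,
                     int n_sims, double base_seed, int max_steps) {
  Xoshiro256pp rng(stream_seed(base_seed, origin));
  std::vector<int> counts(n_nodes, 0);
  std::vector<int> last_sim(n_nodes, -1);
  const int* rp = INTEGER(row_ptr);
  const int* ci = INTEGER(col_idx);
  const double* cw = REAL(cum);
  int cap_hits = 0;

  for (int s = 0; s < n_sims; ++s) {
    int k = origin;
    int steps = 0;
    while (steps < max_steps) {
      int nxt = step_from(k, rp, ci, cw, rng);
      if (nxt < 0) break;
      k = nxt;
      ++steps;
      if (k != origin && last_sim[k] != s) {
        last_sim[k] = s;
        ++counts[k];
      }
    }
    if (steps >= max_steps) ++cap_hits;
  }
  return List::create(_["counts"] = IntegerVector(counts.begin(), counts.end()),
                      _["cap_hits"] = cap_hits);
}

// Simulate a single walk and return the visited sequence after the origin.
// termination: 0 = terminal draw, 1 = node with no outgoing travel,
// 2 = step cap reached.
// [[Rcpp::export]]
List cpp_walk_path(IntegerVector row_ptr, IntegerVector col_idx,
                   NumericVector cum, int origin, double base_seed,
                   int max_steps) {
  Xoshiro256pp rng(stream_seed(base_seed, origin));
  const int* rp = INTEGER(row_ptr);
  const int* ci = INTEGER(col_idx);
  const double* cw = REAL(cum);
  std::vector<int> path;
  int k = origin;
  int termination = 2;
  int steps = 0;
  while (steps < max_steps) {
    int nxt = step_from(k, rp, ci, cw, rng);
    if (nxt == -1) { termination = 0; break; }
    if (nxt == -2) { termination = 1; break; }
    k = nxt;
    path.push_back(k);
    ++steps;
  }
  return List::create(_["path"] = IntegerVector(path.begin(), path.end()),
                      _["termination"] = termination);
}
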