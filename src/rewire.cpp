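// Metropolis-Hastings rewiring over degree-preserving double-edge swaps,
// targeting exp(theta * gwesp(Y; tau)) at fixed per-node degrees.
//
// Adjacency is kept as sorted vectors (cache-friendly intersection by
// two-pointer merge) and the shared-partner count of every extant edge is
// maintained incrementally in a hash map, so the gwesp change of an edge
// insertion/removal needs one neighbourhood intersection plus O(#common
// neighbours) map updates. Draws from R's RNG so a single set.seed()
// governs reproducibility.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

inline std::uint64_t pair_key(int a, int b) {
  if (a > b) std::swap(a, b);
  return (static_cast<std::uint64_t>(a) << 32) | static_cast<std::uint32_t>(b);
}

// fixed-capacity open-addressing map from edge key to shared-partner
// count (linear probing, backward-shift deletion). The number of extant
// edges is invariant under double-edge swaps, so capacity is set once;
// key 0 never occurs for a simple graph's edge (a < b implies b > 0) and
// serves as the empty marker. Flat storage avoids the per-node
// allocation churn a tree/node-based map would pay on every swap.
class SpMap {
public:
  explicit SpMap(std::size_t n_entries) {
    std::size_t cap = 16;
    while (cap < 4 * n_entries) cap <<= 1;
    mask_ = cap - 1;
    keys_.assign(cap, 0);
    vals_.assign(cap, 0);
  }
  static inline std::uint64_t mix(std::uint64_t x) {  // splitmix64 finaliser
    x += 0x9e3779b97f4a7c15ULL;
    x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
    x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
    return x ^ (x >> 31);
  }
  inline std::size_t slot_of(std::uint64_t key) const {
    std::size_t i = mix(key) & mask_;
    while (keys_[i] != 0 && keys_[i] != key) i = (i + 1) & mask_;
    return i;
  }
  // reference to the value, inserting the key if absent
  inline int &operator[](std::uint64_t key) {
    std::size_t i = slot_of(key);
    keys_[i] = key;
    return vals_[i];
  }
  inline int get(std::uint64_t key) const { return vals_[slot_of(key)]; }
  void erase(std::uint64_t key) {
    std::size_t i = slot_of(key);
    if (keys_[i] == 0) return;
    keys_[i] = 0;
    std::size_t j = i;
    for (;;) {  // backward shift to keep probe chains intact
      j = (j + 1) & mask_;
      if (keys_[j] == 0) break;
      std::size_t k = mix(keys_[j]) & mask_;
      if (((j - k) & mask_) >= ((j - i) & mask_)) {
        keys_[i] = keys_[j];
        vals_[i] = vals_[j];
        keys_[j] = 0;
        i = j;
      }
    }
  }
  template <typename F> void for_each(F f) const {
    for (std::size_t i = 0; i <= mask_; ++i)
      if (keys_[i] != 0) f(vals_[i]);
  }

private:
  std::vector<std::uint64_t> keys_;
  std::vector<int> vals_;
  std::size_t mask_;
};

class GwespGraph {
public:
  double etau, base;  // e^tau and 1 - e^-tau
  std::vector<std::vector<int>> adj;  // sorted neighbour lists
  SpMap sp_map;                       // edge -> shared partners
  std::vector<double> powtab;         // base^s, grown lazily

  GwespGraph(int n, double tau, std::size_t m) : adj(n), sp_map(m) {
    etau = std::exp(tau);
    base = 1.0 - std::exp(-tau);
    powtab.push_back(1.0);
  }

  // weight of one edge with s shared partners
  inline double phi(int s) {
    if (s <= 0) return 0.0;
    while (static_cast<int>(powtab.size()) <= s)
      powtab.push_back(powtab.back() * base);
    return etau * (1.0 - powtab[s]);
  }

  inline bool has(int a, int b) const {
    const std::vector<int> &A = adj[a];
    return std::binary_search(A.begin(), A.end(), b);
  }

  // common neighbours of a and b by sorted merge
  void common(int a, int b, std::vector<int> &out) const {
    out.clear();
    const std::vector<int> &A = adj[a], &B = adj[b];
    std::size_t i = 0, j = 0;
    while (i < A.size() && j < B.size()) {
      if (A[i] < B[j]) ++i;
      else if (A[i] > B[j]) ++j;
      else { out.push_back(A[i]); ++i; ++j; }
    }
  }

  inline void vec_insert(std::vector<int> &v, int x) {
    v.insert(std::lower_bound(v.begin(), v.end(), x), x);
  }
  inline void vec_erase(std::vector<int> &v, int x) {
    v.erase(std::lower_bound(v.begin(), v.end(), x));
  }

  // add edge (a,b), maintain sp_map; return the gwesp change
  double add_edge(int a, int b) {
    common(a, b, scratch_);
    double d = 0.0;
    for (int z : scratch_) {  // edges (a,z) and (b,z) gain a shared partner
      for (int x : {a, b}) {
        int &s = sp_map[pair_key(x, z)];
        d += phi(s + 1) - phi(s);
        ++s;
      }
    }
    int s_ab = static_cast<int>(scratch_.size());
    d += phi(s_ab);
    sp_map[pair_key(a, b)] = s_ab;
    vec_insert(adj[a], b);
    vec_insert(adj[b], a);
    return d;
  }

  // remove edge (a,b); return the gwesp change
  double remove_edge(int a, int b) {
    vec_erase(adj[a], b);
    vec_erase(adj[b], a);
    common(a, b, scratch_);
    std::uint64_t key = pair_key(a, b);
    double d = -phi(sp_map.get(key));
    sp_map.erase(key);
    for (int z : scratch_) {
      for (int x : {a, b}) {
        int &s = sp_map[pair_key(x, z)];
        d += phi(s - 1) - phi(s);
        --s;
      }
    }
    return d;
  }

  double full_gwesp() {
    double u = 0.0;
    sp_map.for_each([&](int s) { u += phi(s); });
    return u;
  }

private:
  std::vector<int> scratch_;
};

// load a 1-based edge matrix; fills adjacency and the sp map
void load_edges(GwespGraph &G, const IntegerMatrix &edges,
                std::vector<std::pair<int, int>> &el) {
  int m = edges.nrow();
  el.resize(m);
  for (int i = 0; i < m; ++i) {
    int a = edges(i, 0) - 1, b = edges(i, 1) - 1;
    el[i] = {a, b};
    G.adj[a].push_back(b);
    G.adj[b].push_back(a);
  }
  for (auto &v : G.adj) std::sort(v.begin(), v.end());
  std::vector<int> tmp;
  for (const auto &e : el) {
    G.common(e.first, e.second, tmp);
    G.sp_map[pair_key(e.first, e.second)] = static_cast<int>(tmp.size());
  }
}

}  // namespace

// Full gwesp statistic of an edge list (1-based node indices).
// [[Rcpp::export]]
double cpp_gwesp(IntegerMatrix edges, int n_nodes, double tau) {
  GwespGraph G(n_nodes, tau, edges.nrow());
  std::vector<std::pair<int, int>> el;
  load_edges(G, edges, el);
  return G.full_gwesp();
}

// [[Rcpp::export]]
List cpp_rewire(IntegerMatrix edges, int n_nodes, double tau, double theta,
                double burnin, bool verbose = false) {
  GwespGraph G(n_nodes, tau, edges.nrow());
  std::vector<std::pair<int, int>> el;
  load_edges(G, edges, el);
  int m = static_cast<int>(el.size());
  double u = G.full_gwesp();
  long total = static_cast<long>(burnin);
  long accepted = 0, invalid = 0;

  if (m >= 2) {
    for (long it = 0; it < total; ++it) {
      if ((it & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
      // two distinct edges, uniformly
      int i = static_cast<int>(unif_rand() * m);
      if (i >= m) i = m - 1;
      int j = static_cast<int>(unif_rand() * (m - 1));
      if (j >= m - 1) j = m - 2;
      if (j >= i) ++j;
      int a = el[i].first, b = el[i].second;
      int c = el[j].first, d = el[j].second;
      int p1, q1, p2, q2;  // proposed replacement edges
      if (unif_rand() < 0.5) {
        p1 = a; q1 = d; p2 = c; q2 = b;
      } else {
        p1 = a; q1 = c; p2 = b; q2 = d;
      }
      double delta = G.remove_edge(a, b) + G.remove_edge(c, d);
      bool ok = p1 != q1 && p2 != q2 &&
                !((p1 == p2 && q1 == q2) || (p1 == q2 && q1 == p2)) &&
                !G.has(p1, q1) && !G.has(p2, q2);
      if (!ok) {
        ++invalid;
        G.add_edge(a, b);
        G.add_edge(c, d);
        continue;
      }
      delta += G.add_edge(p1, q1) + G.add_edge(p2, q2);
      double log_acc = theta * delta;
      if (log_acc >= 0.0 || unif_rand() < std::exp(log_acc)) {
        el[i] = {p1, q1};
        el[j] = {p2, q2};
        u += delta;
        ++accepted;
      } else {
        G.remove_edge(p1, q1);
        G.remove_edge(p2, q2);
        G.add_edge(a, b);
        G.add_edge(c, d);
      }
      if (verbose && ((it + 1) % 10000 == 0))
        Rprintf("proposals %ld  accept-rate %.3f  gwesp %.2f\n", it + 1,
                accepted / static_cast<double>(it + 1), u);
    }
  }

  IntegerMatrix out(m, 2);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = el[i].first + 1;
    out(i, 1) = el[i].second + 1;
  }
  return List::create(_["edges"] = out,
                      _["accepted"] = static_cast<double>(accepted),
                      _["invalid"] = static_cast<double>(invalid),
                      _["proposals"] = static_cast<double>(total),
                      _["gwesp"] = u);
}
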