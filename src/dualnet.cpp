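#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Adjacency is passed in CSR form: ptr has length n+1, idx has length 2|E|,
// both 0-based. All RNG draws go through R's unif_rand() so results are
// reproducible under set.seed().

static inline int uf_find(std::vector<int>& par, int x) {
  while (par[x] != x) { par[x] = par[par[x]]; x = par[x]; }
  return x;
}

static inline void uf_union(std::vector<int>& par, std::vector<long>& sz,
                            int a, int b) {
  a = uf_find(par, a); b = uf_find(par, b);
  if (a == b) return;
  if (sz[a] < sz[b]) std::swap(a, b);
  par[b] = a; sz[a] += sz[b];
}

// Largest-cluster trajectories S_A(t), S_I(t) for t = 0..t_max under a
// removal sequence. The Idle side is tracked forward (removed nodes join an
// incremental union-find); the Active side is tracked over the reversed
// sequence so that both directions are pure insertions and the running
// maximum component size is monotone.
// [[Rcpp::export]]
List dual_traj_cpp(IntegerVector ptr, IntegerVector idx, IntegerVector seq,
                   int n) {
  const int tmax = seq.size();
  IntegerVector SA(tmax + 1), SI(tmax + 1);

  { // Idle network, forward in time
    std::vector<int> par(n, -1);
    std::vector<long> sz(n, 0);
    long best = 0;
    SI[0] = 0;
    for (int t = 0; t < tmax; ++t) {
      int u = seq[t];
      par[u] = u; sz[u] = 1;
      for (int j = ptr[u]; j < ptr[u + 1]; ++j) {
        int v = idx[j];
        if (par[v] >= 0) uf_union(par, sz, u, v);
      }
      int r = uf_find(par, u);
      if (sz[r] > best) best = sz[r];
      SI[t + 1] = (int)best;
    }
  }

  { // Active network, reversed (start from the t_max state, re-activate)
    std::vector<int> par(n, -1);
    std::vector<long> sz(n, 0);
    std::vector<char> removed(n, 0);
    for (int t = 0; t < tmax; ++t) removed[seq[t]] = 1;
    long best = 0;
    for (int u = 0; u < n; ++u)
      if (!removed[u]) { par[u] = u; sz[u] = 1; }
    for (int u = 0; u < n; ++u) {
      if (removed[u]) continue;
      for (int j = ptr[u]; j < ptr[u + 1]; ++j) {
        int v = idx[j];
        if (v > u && !removed[v]) uf_union(par, sz, u, v);
      }
    }
    for (int u = 0; u < n; ++u) {
      if (removed[u]) continue;
      int r = uf_find(par, u);
      if (sz[r] > best) best = sz[r];
    }
    SA[tmax] = (int)best;
    for (int t = tmax - 1; t >= 0; --t) {
      int u = seq[t];
      par[u] = u; sz[u] = 1;
      for (int j = ptr[u]; j < ptr[u + 1]; ++j) {
        int v = idx[j];
        if (par[v] >= 0) uf_union(par, sz, u, v);
      }
      int r = uf_find(par, u);
      if (sz[r] > best) best = sz[r];
      SA[t] = (int)best;
    }
  }
  return List::create(_["S_A"] = SA, _["S_I"] = SI);
}

// Fenwick tree over integer weights: exact degree-proportional sampling.
static inline void fen_add(std::vector<long long>& f, int n, int i,
                           long long d) {
  for (; i <= n; i += i & (-i)) f[i] += d;
}

// Largest pos with prefix(pos) <= target; the selected item is pos (0-based).
static inline int fen_search(const std::vector<long long>& f, int n,
                             long long target) {
  int pos = 0;
  int logn = 1;
  while ((1 << logn) <= n) ++logn;
  for (int pw = 1 << logn; pw > 0; pw >>= 1) {
    int np = pos + pw;
    if (np <= n && f[np] <= target) { pos = np; target -= f[np]; }
  }
  return pos;
}

// Degree-proportional targeted attack. Weights are integer degrees kept in a
// Fenwick tree; `current` decrements a removed node's active neighbours so
// weights always equal degrees within the current Active Network. When all
// active weights are zero the draw falls back to uniform over active nodes.
// Returns a full permutation, 0-based.
// [[Rcpp::export]]
IntegerVector ta_plan_cpp(IntegerVector ptr, IntegerVector idx, int n,
                          bool current) {
  std::vector<long long> w(n), f(n + 1, 0);
  long long total = 0;
  for (int u = 0; u < n; ++u) {
    w[u] = ptr[u + 1] - ptr[u];
    total += w[u];
    if (w[u]) fen_add(f, n, u + 1, w[u]);
  }
  std::vector<int> set(n), pos(n);
  for (int u = 0; u < n; ++u) { set[u] = u; pos[u] = u; }
  int nact = n;
  std::vector<char> act(n, 1);
  IntegerVector out(n);
  for (int step = 0; step < n; ++step) {
    int u;
    if (total > 0) {
      long long target = (long long)(unif_rand() * (double)total);
      if (target >= total) target = total - 1;
      if (target < 0) target = 0;
      u = fen_search(f, n, target);
    } else {
      int j = (int)(unif_rand() * nact);
      if (j >= nact) j = nact - 1;
      u = set[j];
    }
    out[step] = u;
    if (w[u] > 0) { fen_add(f, n, u + 1, -w[u]); total -= w[u]; w[u] = 0; }
    act[u] = 0;
    int pu = pos[u], last = set[nact - 1];
    set[pu] = last; pos[last] = pu; --nact;
    if (current) {
      for (int j = ptr[u]; j < ptr[u + 1]; ++j) {
        int v = idx[j];
        if (act[v] && w[v] > 0) { fen_add(f, n, v + 1, -1); --w[v]; --total; }
      }
    }
  }
  return out;
}

// Random spreading: first removal uniform over all nodes; afterwards uniform
// over active nodes adjacent (in the original graph) to at least one idle
// node. If the frontier is empty (disconnected graph) the walk restarts
// uniformly over active nodes. Returns a full permutation, 0-based.
// [[Rcpp::export]]
IntegerVector rs_plan_cpp(IntegerVector ptr, IntegerVector idx, int n) {
  std::vector<int> aset(n), apos(n);
  for (int u = 0; u < n; ++u) { aset[u] = u; apos[u] = u; }
  int nact = n;
  std::vector<int> fset; fset.reserve(n);
  std::vector<int> fpos(n, -1);
  std::vector<char> act(n, 1);
  IntegerVector out(n);
  for (int step = 0; step < n; ++step) {
    int u;
    if (fset.empty()) {
      int j = (int)(unif_rand() * nact);
      if (j >= nact) j = nact - 1;
      u = aset[j];
    } else {
      int fs = (int)fset.size();
      int j = (int)(unif_rand() * fs);
      if (j >= fs) j = fs - 1;
      u = fset[j];
    }
    out[step] = u;
    act[u] = 0;
    { int pu = apos[u], last = aset[nact - 1];
      aset[pu] = last; apos[last] = pu; --nact; }
    if (fpos[u] >= 0) {
      int pu = fpos[u], last = fset.back();
      fset[pu] = last; fpos[last] = pu; fset.pop_back(); fpos[u] = -1;
    }
    for (int j = ptr[u]; j < ptr[u + 1]; ++j) {
      int v = idx[j];
      if (act[v] && fpos[v] < 0) { fpos[v] = (int)fset.size(); fset.push_back(v); }
    }
  }
  return out;
}
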