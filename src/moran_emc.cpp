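#include <Rcpp.h>
#include <random>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Embedded-Markov-chain Monte Carlo for the Moran birth-death invasion
// process.  adj_idx/adj_ptr: CSR adjacency (0-based); r: invader fitness;
// trials: independent runs, each from one uniformly chosen initial
// mutant; returns the number of runs that ended in fixation.
//
// Per-node event weights live in a flat array with an incrementally
// maintained total, so one step costs O(deg(victim)) for the update
// plus one O(N) prefix scan for the sample -- faster than a heap or
// Fenwick tree at the network orders this package targets (<= a few
// thousand nodes).  The running total is refreshed from scratch
// periodically to keep floating-point drift bounded.
// [[Rcpp::export]]
List cpp_emc_fixation(IntegerVector adj_idx, IntegerVector adj_ptr,
                      double r, int trials, int seed) {
  const int N = adj_ptr.size() - 1;
  std::vector<int> deg(N);
  std::vector<double> inv_deg(N);
  for (int i = 0; i < N; ++i) {
    deg[i] = adj_ptr[i + 1] - adj_ptr[i];
    inv_deg[i] = 1.0 / deg[i];
  }

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  auto runif = [&rng]() { return (rng() >> 11) * 0x1.0p-53; };

  std::vector<double> w(N, 0.0);
  std::vector<uint8_t> mut(N);
  std::vector<int> mnb(N);          // mutant neighbours per node
  std::vector<int> touched;         // nodes whose counts changed this trial
  touched.reserve(4 * N);
  double W = 0.0;

  // two-level prefix structure: per-block weight sums make sampling
  // O(sqrt N) while keeping updates O(1)
  const int SHIFT = 4, BS = 1 << SHIFT;
  const int NB = (N + BS - 1) >> SHIFT;
  std::vector<double> bsum(NB, 0.0);

  auto set_weight = [&](int u) {
    // w[u] = fitness of u times its share of opposite-type neighbours
    double nw = mut[u] ? r * (deg[u] - mnb[u]) * inv_deg[u]
                       : mnb[u] * inv_deg[u];
    double d = nw - w[u];
    W += d;
    bsum[u >> SHIFT] += d;
    w[u] = nw;
  };

  long long fixed = 0;
  double total_steps = 0.0;
  for (int t = 0; t < trials; ++t) {
    for (int u : touched) {
      mut[u] = 0; mnb[u] = 0;
      bsum[u >> SHIFT] -= w[u];
      w[u] = 0.0;
    }
    touched.clear();
    W = 0.0;
    std::fill(bsum.begin(), bsum.end(), 0.0);

    int m0 = (int)(runif() * N);
    if (m0 == N) m0 = N - 1;
    mut[m0] = 1;
    touched.push_back(m0);
    set_weight(m0);
    for (int j = adj_ptr[m0]; j < adj_ptr[m0 + 1]; ++j) {
      int v = adj_idx[j];
      touched.push_back(v);
      ++mnb[v];
      set_weight(v);
    }
    int nm = 1;
    long long step = 0;
    while (nm > 0 && nm < N) {
      if ((++step & 0xFFF) == 0) {       // periodic drift refresh
        W = 0.0;
        for (int b = 0; b < NB; ++b) {
          double s = 0.0;
          int hi = std::min(N, (b + 1) << SHIFT);
          for (int i = b << SHIFT; i < hi; ++i) s += w[i];
          bsum[b] = s;
          W += s;
        }
      }
      double x = runif() * W;
      int u = -1;
      double acc = 0.0;
      int b = 0;
      for (; b < NB; ++b) {
        if (x < acc + bsum[b]) break;
        acc += bsum[b];
      }
      if (b < NB) {
        int hi = std::min(N, (b + 1) << SHIFT);
        for (int i = b << SHIFT; i < hi; ++i) {
          acc += w[i];
          if (x < acc) { u = i; break; }
        }
      }
      if (u < 0) {                        // round-off: take last active node
        for (int i = N - 1; i >= 0; --i) if (w[i] > 0.0) { u = i; break; }
        if (u < 0) break;                 // no active node: numerical dead end
      }
      // victim: uniform among opposite-type neighbours of u
      int k = mut[u] ? deg[u] - mnb[u] : mnb[u];
      if (k <= 0) continue;
      int pick = (int)(runif() * k);
      if (pick == k) pick = k - 1;
      int v = -1, cnt = -1;
      for (int j = adj_ptr[u]; j < adj_ptr[u + 1]; ++j) {
        int ww = adj_idx[j];
        if (mut[ww] != mut[u]) {
          if (++cnt == pick) { v = ww; break; }
        }
      }
      // v adopts u's type
      int delta = mut[u] ? +1 : -1;
      mut[v] = mut[u];
      nm += delta;
      set_weight(v);
      for (int j = adj_ptr[v]; j < adj_ptr[v + 1]; ++j) {
        int ww = adj_idx[j];
        if (mnb[ww] == 0 && delta > 0) touched.push_back(ww);
        mnb[ww] += delta;
        set_weight(ww);
      }
      total_steps += 1.0;
    }
    if (nm == N) ++fixed;
  }
  return List::create(_["fixed"] = (double)fixed,
                      _["trials"] = trials,
                      _["mean_steps"] = total_steps / trials);
}

// Degree-preserving randomisation by double-edge swaps with windowed
// connectivity checks.  edges: E x 2 matrix of 0-based endpoints.
// Returns the rewired edge list and the number of true swaps done.
// [[Rcpp::export]]
List cpp_swap_randomize(IntegerMatrix edges, int n_nodes, int n_swaps,
                        int window, int max_tries, int seed) {
  const int E = edges.nrow();
  std::vector<int> ea(E), eb(E);
  std::unordered_set<long long> have;
  have.reserve(E * 2);
  auto key = [n_nodes](int u, int v) -> long long {
    if (u > v) std::swap(u, v);
    return (long long)u * n_nodes + v;
  };
  for (int i = 0; i < E; ++i) {
    ea[i] = edges(i, 0); eb[i] = edges(i, 1);
    have.insert(key(ea[i], eb[i]));
  }

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  auto ri = [&](int n) { int x = (int)(unif(rng) * n); return x == n ? n - 1 : x; };

  std::vector<int> snap_a(ea), snap_b(eb);  // last connected checkpoint
  std::unordered_set<long long> snap_have(have);

  // BFS connectivity over the current edge list
  std::vector<int> head(n_nodes), nxt(2 * E), to(2 * E), queue(n_nodes);
  auto connected = [&]() -> bool {
    std::fill(head.begin(), head.end(), -1);
    int m = 0;
    for (int i = 0; i < E; ++i) {
      to[m] = eb[i]; nxt[m] = head[ea[i]]; head[ea[i]] = m; ++m;
      to[m] = ea[i]; nxt[m] = head[eb[i]]; head[eb[i]] = m; ++m;
    }
    std::vector<uint8_t> seen(n_nodes, 0);
    int qh = 0, qt = 0;
    queue[qt++] = 0; seen[0] = 1;
    int cnt = 1;
    while (qh < qt) {
      int u = queue[qh++];
      for (int e = head[u]; e != -1; e = nxt[e]) {
        if (!seen[to[e]]) { seen[to[e]] = 1; queue[qt++] = to[e]; ++cnt; }
      }
    }
    return cnt == n_nodes;
  };

  long long done = 0, attempts = 0;
  const long long budget = (long long)n_swaps * std::max(1, max_tries);
  int since_check = 0;
  while (done < n_swaps && attempts < budget) {
    ++attempts;
    int i = ri(E), j = ri(E);
    if (i == j) continue;
    int a = ea[i], b = eb[i], c = ea[j], d = eb[j];
    if (unif(rng) < 0.5) std::swap(c, d);
    // propose (a,b),(c,d) -> (a,d),(c,b)
    if (a == d || c == b || a == c || b == d) continue;
    if (have.count(key(a, d)) || have.count(key(c, b))) continue;
    have.erase(key(a, b)); have.erase(key(c, d));
    have.insert(key(a, d)); have.insert(key(c, b));
    eb[i] = d; eb[j] = b; ea[i] = a; ea[j] = c;
    ++done;
    if (++since_check >= window || done == n_swaps) {
      if (connected()) {
        snap_a = ea; snap_b = eb; snap_have = have;
      } else {
        ea = snap_a; eb = snap_b; have = snap_have;
        done -= since_check;  // the whole window is rolled back
      }
      since_check = 0;
    }
  }
  IntegerMatrix out(E, 2);
  for (int i = 0; i < E; ++i) { out(i, 0) = ea[i]; out(i, 1) = eb[i]; }
  return List::create(_["edges"] = out, _["swaps_done"] = (double)done);
}
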