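#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Per-snapshot connected components (union-find). Contacts carry 0-based
// snapshot indices and 0-based agent indices. Membership is stored
// column-major as mem[a + s * N]: the 0-based event id of agent a in snapshot
// s. Event ids are contiguous within a snapshot and numbered in order of
// smallest member index, so the labelling is deterministic.
// ---------------------------------------------------------------------------

static int uf_find(std::vector<int>& p, int x) {
  while (p[x] != x) {
    p[x] = p[p[x]];
    x = p[x];
  }
  return x;
}

// `order` must hold contact indices sorted by snapshot; `skip` (0-based agent
// index, or -1) drops every contact touching that agent.
static void fill_membership(const int* snap, const int* a, const int* b,
                            const std::vector<int>& order, int n_agents,
                            int n_snapshots, int skip,
                            std::vector<int>& mem) {
  mem.resize(static_cast<size_t>(n_agents) * n_snapshots);
  std::vector<int> parent(n_agents), label(n_agents);
  size_t k = 0;
  const size_t m = order.size();
  for (int s = 0; s < n_snapshots; ++s) {
    for (int i = 0; i < n_agents; ++i) parent[i] = i;
    while (k < m && snap[order[k]] == s) {
      const int i = order[k];
      ++k;
      if (a[i] == skip || b[i] == skip) continue;
      int ra = uf_find(parent, a[i]);
      int rb = uf_find(parent, b[i]);
      if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
    }
    std::fill(label.begin(), label.end(), -1);
    int next_id = 0;
    int* col = &mem[static_cast<size_t>(s) * n_agents];
    for (int i = 0; i < n_agents; ++i) {
      const int r = uf_find(parent, i);
      if (label[r] < 0) label[r] = next_id++;
      col[i] = label[r];
    }
  }
}

static std::vector<int> snapshot_order(const int* snap, int m) {
  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int i, int j) { return snap[i] < snap[j]; });
  return ord;
}

// [[Rcpp::export]]
IntegerMatrix cpp_event_membership(IntegerVector snap, IntegerVector a,
                                   IntegerVector b, int n_agents,
                                   int n_snapshots) {
  std::vector<int> ord = snapshot_order(snap.begin(), snap.size());
  std::vector<int> mem;
  fill_membership(snap.begin(), a.begin(), b.begin(), ord, n_agents,
                  n_snapshots, -1, mem);
  IntegerMatrix out(n_agents, n_snapshots);
  std::copy(mem.begin(), mem.end(), out.begin());
  return out;
}

// ---------------------------------------------------------------------------
// Traced-agent counts over the window [t0, t0 + dt) of whole snapshots.
// Works backwards through the window keeping, per event, the bitset of agents
// traceable forward from that event; linking follows the event-graph rule
// (an event at s feeds every event at s+1 sharing an agent).
// ---------------------------------------------------------------------------

static void trace_counts_window(const std::vector<int>& mem, int n_agents,
                                int t0, int dt, std::vector<int>& counts) {
  const int N = n_agents;
  const int words = (N + 63) / 64;
  std::vector<uint64_t> S_cur, S_next;

  for (int s = t0 + dt - 1; s >= t0; --s) {
    const int* col = &mem[static_cast<size_t>(s) * N];
    int nev = 0;
    for (int i = 0; i < N; ++i)
      if (col[i] + 1 > nev) nev = col[i] + 1;
    S_cur.assign(static_cast<size_t>(nev) * words, 0ULL);
    for (int i = 0; i < N; ++i)
      S_cur[static_cast<size_t>(col[i]) * words + i / 64] |=
          (1ULL << (i % 64));
    if (s < t0 + dt - 1) {
      const int* nxt = &mem[static_cast<size_t>(s + 1) * N];
      for (int i = 0; i < N; ++i) {
        uint64_t* dst = &S_cur[static_cast<size_t>(col[i]) * words];
        const uint64_t* src = &S_next[static_cast<size_t>(nxt[i]) * words];
        for (int w = 0; w < words; ++w) dst[w] |= src[w];
      }
    }
    S_next.swap(S_cur);
  }

  const int* col0 = &mem[static_cast<size_t>(t0) * N];
  counts.assign(N, 0);
  for (int j = 0; j < N; ++j) {
    const uint64_t* S = &S_next[static_cast<size_t>(col0[j]) * words];
    int c = 0;
    for (int w = 0; w < words; ++w)
      c += __builtin_popcountll(S[w]);
    counts[j] = c;
  }
}

static std::vector<int> as_vec(const IntegerMatrix& mem) {
  return std::vector<int>(mem.begin(), mem.end());
}

// [[Rcpp::export]]
IntegerVector cpp_trace_counts(IntegerMatrix mem, int t0, int dt) {
  std::vector<int> counts;
  trace_counts_window(as_vec(mem), mem.nrow(), t0, dt, counts);
  return wrap(counts);
}

// Sum of traced counts over all sources, one value per start snapshot; the
// mean traceability at start t is this sum divided by N^2.
// [[Rcpp::export]]
NumericVector cpp_trace_count_sums(IntegerMatrix mem, IntegerVector t_starts,
                                   int dt) {
  const std::vector<int> m = as_vec(mem);
  const int nt = t_starts.size();
  NumericVector out(nt);
  std::vector<int> counts;
  for (int u = 0; u < nt; ++u) {
    trace_counts_window(m, mem.nrow(), t_starts[u], dt, counts);
    double s = 0;
    for (size_t i = 0; i < counts.size(); ++i) s += counts[i];
    out[u] = s;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Leave-one-out sweep: traced-count sums per start snapshot for the intact
// network (row 0) and after removing all contacts of each probed agent
// (row k for probes[k-1]). One pass over the contact arrays per probe; the
// full sweep over all agents costs O(T * N^2) word operations.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_impact_sums(IntegerVector snap, IntegerVector a,
                              IntegerVector b, int n_agents, int n_snapshots,
                              IntegerVector t_starts, int dt,
                              IntegerVector probes) {
  const std::vector<int> ord = snapshot_order(snap.begin(), snap.size());
  const int nt = t_starts.size();
  NumericMatrix out(probes.size() + 1, nt);
  std::vector<int> mem, counts;

  for (int row = 0; row <= probes.size(); ++row) {
    const int skip = row == 0 ? -1 : probes[row - 1];
    fill_membership(snap.begin(), a.begin(), b.begin(), ord, n_agents,
                    n_snapshots, skip, mem);
    for (int u = 0; u < nt; ++u) {
      trace_counts_window(mem, n_agents, t_starts[u], dt, counts);
      double s = 0;
      for (size_t i = 0; i < counts.size(); ++i) s += counts[i];
      out(row, u) = s;
    }
  }
  return out;
}
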