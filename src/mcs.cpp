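#include <Rcpp.h>
#include <chrono>
using namespace Rcpp;

// Connected maximum common (edge) subgraph between two labelled molecular
// graphs, counted in atoms. McGregor-style branch and bound: at each step one
// frontier atom of graph 1 (unmapped, adjacent to the mapped core) is either
// mapped to a compatible atom of graph 2 or excluded from the current subtree.
// Atom/bond label codes are prepared on the R side (element, ring membership,
// bond order), so matching here is plain integer equality. A pair (i, j) may
// join the core when at least one edge to the mapped core exists in both
// graphs with an identical bond label; edges present in only one graph are
// simply not part of the common subgraph.

namespace {

struct Search {
  int n1, n2;
  const int *el1, *el2;
  const int *adj1, *adj2; // column-major n x n bond-label matrices, 0 = none
  std::vector<int> map1;  // G1 atom -> G2 atom or -1
  std::vector<char> used2, forbid1;
  int count = 0, best = 0;
  long nodes = 0;
  bool timed_out = false;
  std::chrono::steady_clock::time_point deadline;

  inline int a1(int i, int j) const { return adj1[i + n1 * j]; }
  inline int a2(int i, int j) const { return adj2[i + n2 * j]; }

  bool time_up() {
    if ((++nodes & 1023) == 0 &&
        std::chrono::steady_clock::now() > deadline)
      timed_out = true;
    return timed_out;
  }

  int frontier_atom() const {
    for (int i = 0; i < n1; ++i) {
      if (map1[i] >= 0 || forbid1[i]) continue;
      for (int u = 0; u < n1; ++u)
        if (map1[u] >= 0 && a1(i, u)) return i;
    }
    return -1;
  }

  void extend() {
    if (count > best) best = count;
    if (time_up()) return;
    // optimistic bound: every remaining allowed atom of G1 could be mapped
    int free1 = 0, free2 = 0;
    for (int i = 0; i < n1; ++i)
      if (map1[i] < 0 && !forbid1[i]) ++free1;
    for (int j = 0; j < n2; ++j)
      if (!used2[j]) ++free2;
    if (count + std::min(free1, free2) <= best) return;

    int i = frontier_atom();
    if (i < 0) return;

    for (int j = 0; j < n2 && !timed_out; ++j) {
      if (used2[j] || el1[i] != el2[j]) continue;
      bool link = false;
      for (int u = 0; u < n1 && !link; ++u) {
        int b1 = (map1[u] >= 0) ? a1(i, u) : 0;
        if (b1 && b1 == a2(j, map1[u])) link = true;
      }
      if (!link) continue;
      map1[i] = j; used2[j] = 1; ++count;
      extend();
      map1[i] = -1; used2[j] = 0; --count;
    }
    if (timed_out) return;
    forbid1[i] = 1;
    extend();
    forbid1[i] = 0;
  }
};

} // namespace

// [[Rcpp::export(name = ".mcs_core")]]
List mcs_core(IntegerVector el1, IntegerMatrix adj1,
              IntegerVector el2, IntegerMatrix adj2,
              double timeout_ms) {
  Search s;
  s.n1 = el1.size(); s.n2 = el2.size();
  s.el1 = INTEGER(el1); s.el2 = INTEGER(el2);
  s.adj1 = INTEGER(adj1); s.adj2 = INTEGER(adj2);
  s.map1.assign(s.n1, -1);
  s.used2.assign(s.n2, 0);
  s.forbid1.assign(s.n1, 0);
  s.deadline = std::chrono::steady_clock::now() +
               std::chrono::microseconds((long long)(timeout_ms * 1000));

  int cap = std::min(s.n1, s.n2);
  // seed on every compatible pair; atoms below the seed are excluded from
  // later seeds so each connected component of the search runs once
  for (int i = 0; i < s.n1 && !s.timed_out && s.best < cap; ++i) {
    for (int j = 0; j < s.n2 && !s.timed_out && s.best < cap; ++j) {
      if (el1[i] != el2[j]) continue;
      s.map1[i] = j; s.used2[j] = 1; s.count = 1;
      s.extend();
      s.map1[i] = -1; s.used2[j] = 0; s.count = 0;
    }
    s.forbid1[i] = 1;
  }
  return List::create(_["size"] = s.best, _["timed_out"] = s.timed_out);
}
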