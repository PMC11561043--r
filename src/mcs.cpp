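// Connected maximum common substructure search over element-labelled
// molecular graphs.  Atoms match on element identity; bonds match whenever
// both molecules have a bond between the mapped atom pairs (bond order and
// aromaticity are deliberately not compared).  Optionally a bond in a ring
// may be required to match a bond in a ring.
//
// Algorithm: McGregor-style backtracking growth of a connected common
// subgraph with an exclusion set to avoid re-enumerating mappings (each
// candidate pair, once fully explored at a search node, is barred from the
// remaining subtree).  Upper bound for pruning: current size plus the
// multiset intersection of unmatched element counts.

#include <Rcpp.h>
#include <chrono>
#include <vector>

using namespace Rcpp;

namespace {

struct SearchState {
  int na, nb;
  const int *la, *lb;          // element labels (small ints)
  const int *adjA, *adjB;      // na*na / nb*nb; 0 none, 1 chain bond, 2 ring bond
  bool ring_match;
  int nlab;
  std::vector<int> cntA, cntB; // unmatched atoms per label
  std::vector<int> mapA, mapB; // -1 when unmapped
  std::vector<char> excluded;  // na*nb candidate-pair exclusion flags
  int best;
  long long nodes;
  bool timed_out;
  std::chrono::steady_clock::time_point deadline;

  bool bond_ok(int bA, int bB) const {
    if (bA == 0 || bB == 0) return false;
    if (ring_match) return bA == bB;
    return true;
  }

  int bound_potential() const {
    int pot = 0;
    for (int l = 0; l < nlab; ++l) pot += std::min(cntA[l], cntB[l]);
    return pot;
  }

  void extend(int cur) {
    if (cur > best) best = cur;
    if (++nodes % 2048 == 0 &&
        std::chrono::steady_clock::now() > deadline) {
      timed_out = true;
    }
    if (timed_out) return;
    if (cur + bound_potential() <= best) return;

    // candidate pairs: both unmapped, same label, adjacent (with a matching
    // bond) to some already-mapped pair; for an empty mapping, all pairs.
    std::vector<int> cands;
    for (int i = 0; i < na; ++i) {
      if (mapA[i] >= 0) continue;
      for (int j = 0; j < nb; ++j) {
        if (mapB[j] >= 0 || la[i] != lb[j]) continue;
        if (excluded[i * nb + j]) continue;
        if (cur > 0) {
          bool conn = false;
          for (int p = 0; p < na && !conn; ++p) {
            if (mapA[p] < 0) continue;
            conn = bond_ok(adjA[i * na + p], adjB[j * nb + mapA[p]]);
          }
          if (!conn) continue;
        }
        cands.push_back(i * nb + j);
      }
    }
    if (cands.empty()) return;

    std::vector<int> newly;
    newly.reserve(cands.size());
    for (int c : cands) {
      if (timed_out) break;
      int i = c / nb, j = c % nb;
      if (cur + bound_potential() <= best) break;
      mapA[i] = j; mapB[j] = i;
      --cntA[la[i]]; --cntB[lb[j]];
      extend(cur + 1);
      mapA[i] = -1; mapB[j] = -1;
      ++cntA[la[i]]; ++cntB[lb[j]];
      excluded[c] = 1;
      newly.push_back(c);
    }
    for (int c : newly) excluded[c] = 0;
  }
};

} // namespace

// [[Rcpp::export]]
List mccs_search(IntegerVector labA, IntegerMatrix adjA,
                 IntegerVector labB, IntegerMatrix adjB,
                 double timeout_s, bool ring_match) {
  int na = labA.size(), nb = labB.size();
  SearchState st;
  st.na = na; st.nb = nb;
  st.ring_match = ring_match;
  int nlab = 0;
  for (int i = 0; i < na; ++i) nlab = std::max(nlab, labA[i] + 1);
  for (int j = 0; j < nb; ++j) nlab = std::max(nlab, labB[j] + 1);
  st.nlab = nlab;
  st.cntA.assign(nlab, 0); st.cntB.assign(nlab, 0);
  for (int i = 0; i < na; ++i) ++st.cntA[labA[i]];
  for (int j = 0; j < nb; ++j) ++st.cntB[labB[j]];
  st.mapA.assign(na, -1); st.mapB.assign(nb, -1);
  st.excluded.assign((size_t)na * nb, 0);
  st.la = INTEGER(labA); st.lb = INTEGER(labB);
  st.adjA = INTEGER(adjA); st.adjB = INTEGER(adjB);
  st.best = 0; st.nodes = 0; st.timed_out = false;
  st.deadline = std::chrono::steady_clock::now() +
      std::chrono::microseconds((long long)(timeout_s * 1e6));
  st.extend(0);
  return List::create(_["mcs_atom_count"] = st.best,
                      _["timed_out"] = st.timed_out,
                      _["nodes"] = (double)st.nodes);
}
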