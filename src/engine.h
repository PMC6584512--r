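#ifndef CISMINE_ENGINE_H
#define CISMINE_ENGINE_H

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <functional>

// Reverse-search state over a fixed undirected graph (0-based ids,
// adjacency lists sorted ascending).
//
// Arrays (all size n except the stacks, which are bounded by n):
//   U    members in insertion order; U[0] is the anchor, back() the utmost
//   C    live candidate array, kept compact: every entry is a valid child
//        of the current search node
//   D    distance from the anchor at first touch (-1 = untouched)
//   P    member of U from which the vertex first entered C (-1 = none)
//   inU  membership flag
//   invV/invSlot   stack of invalidated candidates and the C index they
//        were removed from, so backtracking puts them back exactly
//
// Removal from C swaps the last element into the vacated index; because
// extend/backtrack pairs nest LIFO, replaying the removals in reverse
// restores C bit-exactly.  Keeping C compact (instead of leaving holes)
// is what makes the per-node work proportional to the live candidate
// count rather than to the search depth.
//
// Candidates <= anchor are never admitted: under a root r only sets with
// minimum id r are enumerated, and v > anchor is necessary for validity,
// so filtering at insertion is equivalent to filtering at check time.
class CisEngine {
public:
  int n;
  std::vector<std::vector<int>> adj;
  std::vector<int> U, C, D, P;
  std::vector<char> inU;
  std::vector<int> invV, invSlot;

  struct Frame {
    int v;
    std::size_t slot, addBase, invBase;
  };

  explicit CisEngine(const Rcpp::List& adjList) {
    n = adjList.size();
    adj.resize(n);
    for (int i = 0; i < n; ++i) {
      Rcpp::IntegerVector nb = adjList[i];
      adj[i].reserve(nb.size());
      for (int j = 0; j < nb.size(); ++j) adj[i].push_back(nb[j] - 1);
    }
    D.assign(n, -1);
    P.assign(n, -1);
    inU.assign(n, 0);
  }

  // (D, id) key comparison: is x strictly before v in the child order?
  bool keyLess(int x, int v) const {
    return D[x] < D[v] || (D[x] == D[v] && x < v);
  }

  void swapRemove(std::size_t j) {
    if (j + 1 < C.size()) C[j] = C.back();
    C.pop_back();
  }

  void swapRestore(int v, std::size_t j) {
    if (j == C.size()) {
      C.push_back(v);
    } else {
      C.push_back(C[j]);
      C[j] = v;
    }
  }

  void initRoot(int r) {
    U.clear(); C.clear(); invV.clear(); invSlot.clear();
    D[r] = 0;
    U.push_back(r);
    inU[r] = 1;
    for (int w : adj[r])
      if (w > r) { D[w] = 1; P[w] = r; C.push_back(w); }
  }

  void resetRoot(int r) {
    for (int x : C) { D[x] = -1; P[x] = -1; }
    D[r] = -1;
    inU[r] = 0;
    U.clear(); C.clear();
  }

  // Extend with the candidate in the given slot.  Invalidates every
  // remaining candidate whose (D, id) key precedes the new utmost (it can
  // never pass the child-validity test while this vertex is in U), then
  // appends untouched neighbors > anchor with D = D[v]+1 and P = v.
  Frame extendAt(std::size_t slot) {
    Frame f;
    f.v = C[slot];
    f.slot = slot;
    f.invBase = invV.size();
    swapRemove(slot);
    int v = f.v;
    for (std::size_t j = 0; j < C.size();) {
      int x = C[j];
      if (keyLess(x, v)) {
        invV.push_back(x);
        invSlot.push_back((int)j);
        swapRemove(j); // re-examine the element swapped into j
      } else {
        ++j;
      }
    }
    U.push_back(v);
    inU[v] = 1;
    f.addBase = C.size();
    int anchor = U[0], dv = D[v];
    for (int w : adj[v])
      if (w > anchor && D[w] == -1) {
        D[w] = dv + 1;
        P[w] = v;
        C.push_back(w);
      }
    return f;
  }

  // Exact inverse of extendAt: drop appended candidates (resetting their
  // D/P), undo the invalidation removals in reverse, return the extended
  // vertex to its slot.
  void backtrack(const Frame& f) {
    while (C.size() > f.addBase) {
      int w = C.back();
      C.pop_back();
      D[w] = -1;
      P[w] = -1;
    }
    while (invV.size() > f.invBase) {
      swapRestore(invV.back(), invSlot.back());
      invV.pop_back();
      invSlot.pop_back();
    }
    U.pop_back();
    inU[f.v] = 0;
    swapRestore(f.v, f.slot);
  }
};

#endif
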