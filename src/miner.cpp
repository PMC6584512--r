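#include "engine.h"
#include <algorithm>
#include <string>

using namespace Rcpp;

namespace {

inline int popcnt(const uint64_t* s, int nb) {
  int c = 0;
  for (int i = 0; i < nb; ++i) c += __builtin_popcountll(s[i]);
  return c;
}

inline bool subsetSig(const uint64_t* a, const uint64_t* b, int nb) {
  for (int i = 0; i < nb; ++i)
    if (a[i] & ~b[i]) return false;
  return true;
}

inline bool equalSig(const uint64_t* a, const uint64_t* b, int nb) {
  for (int i = 0; i < nb; ++i)
    if (a[i] != b[i]) return false;
  return true;
}

// Miner over the reverse-search tree restricted to cohesive nodes.
// Signatures are bitsets over d attribute dimensions, kept on a stack
// indexed by |U| (level 0 is the all-ones signature of the empty set).
class Miner {
public:
  CisEngine eng;
  int d, nb, smin;
  bool pruneCov, pruneParent, pruneL1, doTrace;
  std::vector<uint64_t> F;        // n * nb vertex feature bitsets
  std::vector<uint64_t> sigStack; // (n+2) * nb
  std::vector<std::string> lab;
  std::vector<std::vector<int>> outSets;
  std::vector<std::vector<int>> outDims;
  std::vector<std::string> evType, evNode, evVertex, evBy;
  double nodesVisited = 0;

  Miner(const List& adjList, const IntegerMatrix& feat,
        const CharacterVector& labels, int smin_, bool pc, bool pp, bool pl1,
        bool tr)
      : eng(adjList), smin(smin_), pruneCov(pc), pruneParent(pp),
        pruneL1(pl1), doTrace(tr) {
    d = feat.ncol();
    nb = (d + 63) / 64;
    if (nb == 0) nb = 1;
    F.assign((std::size_t)eng.n * nb, 0);
    for (int v = 0; v < eng.n; ++v)
      for (int j = 0; j < d; ++j)
        if (feat(v, j)) F[(std::size_t)v * nb + j / 64] |= 1ULL << (j % 64);
    sigStack.assign((std::size_t)(eng.n + 2) * nb, 0);
    for (int j = 0; j < d; ++j) sigStack[j / 64] |= 1ULL << (j % 64);
    lab.resize(labels.size());
    for (int i = 0; i < labels.size(); ++i) lab[i] = as<std::string>(labels[i]);
  }

  const uint64_t* fv(int v) const { return &F[(std::size_t)v * nb]; }
  uint64_t* level(std::size_t k) { return &sigStack[k * nb]; }

  int supportWith(const uint64_t* sig, int v) const {
    int c = 0;
    const uint64_t* f = fv(v);
    for (int i = 0; i < nb; ++i) c += __builtin_popcountll(sig[i] & f[i]);
    return c;
  }

  std::string nodeString() const {
    std::vector<int> s(eng.U);
    std::sort(s.begin(), s.end());
    std::string out;
    for (std::size_t i = 0; i < s.size(); ++i) {
      if (i) out += ',';
      out += lab[s[i]];
    }
    return out;
  }

  void event(const char* type, const std::string& node, int vertex, int by) {
    if (!doTrace) return;
    evType.push_back(type);
    evNode.push_back(node);
    evVertex.push_back(vertex >= 0 ? lab[vertex] : "");
    evBy.push_back(by >= 0 ? lab[by] : "");
  }

  // A node is maximal iff no graph neighbor of U (candidate, invalidated,
  // pruned, or below the anchor) keeps at least smin cohesive dimensions.
  bool isMaximal(const uint64_t* sig) const {
    for (int u : eng.U)
      for (int w : eng.adj[u])
        if (!eng.inU[w] && supportWith(sig, w) >= smin) return false;
    return true;
  }

  void report(const uint64_t* sig) {
    std::vector<int> s(eng.U);
    std::sort(s.begin(), s.end());
    outSets.push_back(s);
    std::vector<int> dims;
    for (int j = 0; j < d; ++j)
      if (sig[j / 64] >> (j % 64) & 1) dims.push_back(j);
    outDims.push_back(dims);
    event("report", nodeString(), -1, -1);
  }

  void mineRec() {
    ++nodesVisited;
    std::size_t depth = eng.U.size();
    const uint64_t* sig = level(depth);
    if (isMaximal(sig)) report(sig);

    // cohesive valid children, sorted by closeness to the anchor (D, id)
    std::vector<std::pair<std::size_t, int>> cands;
    for (std::size_t j = 0; j < eng.C.size(); ++j) {
      int v = eng.C[j];
      if (supportWith(sig, v) >= smin) cands.push_back({j, v});
    }
    std::sort(cands.begin(), cands.end(),
              [&](const std::pair<std::size_t, int>& a,
                  const std::pair<std::size_t, int>& b) {
                if (eng.D[a.second] != eng.D[b.second])
                  return eng.D[a.second] < eng.D[b.second];
                return a.second < b.second;
              });

    std::vector<int> kept;                 // explored siblings, in order
    std::vector<std::vector<uint64_t>> keptSig;
    for (std::size_t i = 0; i < cands.size(); ++i) {
      int v = cands[i].second;
      std::vector<uint64_t> childSig(nb);
      const uint64_t* f = fv(v);
      for (int b = 0; b < nb; ++b) childSig[b] = sig[b] & f[b];
      if (pruneCov) {
        bool covered = false;
        for (std::size_t k = 0; k < kept.size() && !covered; ++k)
          if (subsetSig(childSig.data(), keptSig[k].data(), nb)) {
            event("covered_sibling", nodeString(), v, kept[k]);
            covered = true;
          }
        if (covered) continue;
      }
      kept.push_back(v);
      keptSig.push_back(childSig);
      CisEngine::Frame fr = eng.extendAt(cands[i].first);
      std::copy(childSig.begin(), childSig.end(), level(depth + 1));
      mineRec();
      eng.backtrack(fr);
      if (pruneParent && equalSig(childSig.data(), sig, nb)) {
        if (i + 1 < cands.size())
          event("parent_identical_cutoff", nodeString(), v, -1);
        break;
      }
    }
  }

  void run() {
    for (int r = 0; r < eng.n; ++r) {
      if (popcnt(fv(r), nb) < smin) continue;
      if (pruneL1) {
        bool pruned = false;
        for (int w : eng.adj[r])
          if (w < r && subsetSig(fv(r), fv(w), nb)) {
            event("level_one_prune", "", r, w);
            pruned = true;
            break;
          }
        if (pruned) continue;
      }
      eng.initRoot(r);
      const uint64_t* base = level(0);
      const uint64_t* f = fv(r);
      uint64_t* s1 = level(1);
      for (int b = 0; b < nb; ++b) s1[b] = base[b] & f[b];
      mineRec();
      eng.resetRoot(r);
    }
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_mine(List adj, IntegerMatrix feat, CharacterVector labels, int smin,
              bool prune_covering, bool prune_parent, bool prune_level_one,
              bool trace) {
  Miner m(adj, feat, labels, smin, prune_covering, prune_parent,
          prune_level_one, trace);
  m.run();
  List sets(m.outSets.size()), dims(m.outDims.size());
  for (std::size_t i = 0; i < m.outSets.size(); ++i) {
    IntegerVector s(m.outSets[i].size());
    for (std::size_t j = 0; j < m.outSets[i].size(); ++j)
      s[j] = m.outSets[i][j] + 1;
    sets[i] = s;
  }
  for (std::size_t i = 0; i < m.outDims.size(); ++i) {
    IntegerVector s(m.outDims[i].size());
    for (std::size_t j = 0; j < m.outDims[i].size(); ++j)
      s[j] = m.outDims[i][j] + 1;
    dims[i] = s;
  }
  return List::create(
      _["sets"] = sets, _["dims"] = dims,
      _["trace"] = List::create(
          _["event"] = wrap(m.evType), _["node"] = wrap(m.evNode),
          _["vertex"] = wrap(m.evVertex), _["by"] = wrap(m.evBy)),
      _["nodes_visited"] = m.nodesVisited);
}
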