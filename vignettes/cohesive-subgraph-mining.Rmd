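---
title: "Enumerating connected induced subgraphs and mining maximal cohesive modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating connected induced subgraphs and mining maximal cohesive modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cismine)
```

## The problem

Many module-discovery methods in network biology need to walk the space of
*connected induced subgraphs* of an interaction network: a vertex set $U$
together with every edge of the input graph $G$ that joins two of its
members, required to be connected. The number of such sets can be
exponential, so the enumeration algorithm matters more than the raw count:
it should emit each set exactly once, with *linear delay* (the time between
two consecutive sets, or until exhaustion, is linear in the graph size) and
linear auxiliary memory, so that downstream filters can consume the stream
without ever materializing it.

`cismine` implements a reverse-search enumerator with those guarantees and,
on top of it, a miner for **maximal cohesive subgraphs** of a binary
vertex-attributed graph $G = (V, E, f)$, $f : V \to \{0,1\}^d$: connected
sets whose members share at least $S_{\min}$ attribute dimensions, with no
cohesive connected strict superset. In a protein-interaction setting, the
attribute bits typically mark dysregulation of a gene across conditions, so
a maximal cohesive subgraph is a connected set of genes jointly affected in
at least $S_{\min}$ conditions.

## Reverse search with an anchor/utmost parent operation

Reverse search arranges all solutions in a tree rooted at the empty set.
The tree is defined by a *parent* operation: for a connected set $U$, let
the *anchor* be its minimum-id vertex and the *utmost* vertex the member
with the longest shortest-path distance to the anchor inside $G(U)$, ties
broken toward the larger id. Deleting the utmost vertex cannot disconnect
$G(U)$ — if it did, some member would have to be strictly farther from the
anchor — so the parent of $U$ is $U$ minus its utmost vertex, and repeated
application reaches the empty set.

Inverting the parent operation gives the child rule. A neighbor $v$ of $U$
with anchor $s$ and utmost vertex $u$ yields a child $U \cup \{v\}$ iff

* $v > s$, and
* $\mathrm{dist}(s, v) > \mathrm{dist}(s, u)$, or
  $\mathrm{dist}(s, v) = \mathrm{dist}(s, u)$ and $v > u$.

Members are therefore appended in strictly increasing $(\mathrm{dist}, id)$
key, and the enumeration is a plain depth-first traversal of the implied
tree, one root per vertex, each root $r$ producing exactly the connected
sets whose minimum id is $r$.

### The distance-array state

The state behind the constant-time child test is a handful of length-$n$
arrays: the member array `U` in insertion order (first entry the anchor,
last the utmost vertex), the candidate array `C`, the distance array `D`
(distance from the anchor, fixed when a vertex first becomes a candidate),
and the parent array `P` (the member from which the vertex first entered
`C`). Extending with a candidate $v$ costs $O(\Delta)$ for the neighbor
scan: untouched neighbors above the anchor enter `C` with
`D = D[v] + 1`, `P = v`.

Two engine-level choices deserve a note:

* **Candidate admission.** Vertices $\le$ anchor are never admitted to
  `C`. The child rule requires $v > s$ under every node of the current
  root, so filtering at insertion time is equivalent to filtering at every
  validity check, and cheaper. Consequently `D`/`P` entries exist only for
  admitted candidates.
* **Distances are never updated.** `D[w]` is assigned once, when $w$ first
  enters `C`. Because members are appended in non-decreasing distance, no
  later extension can create a shortcut to a touched vertex: when $w$ was
  touched, every member within smaller distance was already in $U$.
* **Invalidation with exact restoration.** After extending with $v$, any
  remaining candidate whose $(\mathrm{dist}, id)$ key precedes $v$'s can
  never pass the child test deeper in this subtree (the utmost key only
  grows), so it is moved to a side stack together with its index in `C`,
  and `C` stays compact — the per-node work is proportional to the live
  candidate count, not to the search depth. Removal swaps the last element
  into the vacated slot; since extend/backtrack pairs nest LIFO, replaying
  the removals in reverse on backtrack restores the arrays bit-exactly
  (`state_snapshot()` before an extension and after the matching backtrack
  are `identical()`).

The compiled engine (`count_cis()`, `enumerate_cis()`, `write_cis()`)
recurses once per member, so the C-stack depth is bounded by $n$; a path
graph with $10^4$ vertices (50,005,000 sets) enumerates in a few seconds.
An R-level mirror of the same state machine (`enum_state_new()`,
`state_extend()`, `state_backtrack()`, `is_valid_child()`) exposes every
array for inspection and is what the worked examples and the property
tests drive; a dedicated test checks that both routes emit the same sets.
The two routes may order children differently (the R mirror leaves holes
in `C`, the engine compacts it); both orders are deterministic, and the
set of emitted solutions is identical.

## Mining maximal cohesive subgraphs

A dimension $j$ is *cohesive* for $U$ when every member carries feature
$j$; $A(U)$ is the set of such dimensions, computed incrementally as a
bitwise AND down the search path ($A(\emptyset)$ is all ones). Cohesion
($|A(U)| \ge S_{\min}$) is anti-monotone, so the miner simply restricts
the reverse-search tree to cohesive nodes and reports a node iff no graph
neighbor of $U$ — valid candidate, invalidated candidate, pruned vertex,
or a vertex below the anchor — keeps $S_{\min}$ dimensions when added.
Scanning *all* neighbors matters: the candidate array alone no longer
witnesses non-maximality once branches are pruned. Single-vertex
extensions suffice because any connected cohesive strict superset contains
a neighbor of $U$, and adding that neighbor alone preserves cohesion.

Three prunes remove branches that cannot contain a maximal node:

* **Covering siblings.** Candidates are sorted by closeness to the anchor
  (ascending $(\mathrm{dist}, id)$ — exactly the child order). If an
  earlier kept sibling $x$ satisfies $A(U \cup \{y\}) \subseteq
  A(U \cup \{x\})$, the branch at $y$ is pruned: every maximal superset of
  $U \cup \{y\}$ also admits $x$, and the joint sets are reachable through
  the $x$ branch. Equal signatures are mutual covers; the earlier sibling
  survives, deterministically.
* **Level one.** A root $v$ is skipped when a smaller neighbor $w$ has
  $f(v) \subseteq f(w)$: every cohesive set grown from $v$ stays cohesive
  after adding $w$, so nothing under root $v$ is maximal, and the sets
  containing $w$ live under a smaller root. When two mutual neighbors have
  identical feature vectors the smaller id survives.
* **Parent-identical children.** If a child keeps its parent's full
  signature, the miner recurses into it and skips the remaining siblings
  outright — they are all covered, and the per-sibling subset checks can
  be dropped.

The prunes are heuristics for speed only: a test sweeps all eight on/off
combinations of the three flags over seeded planted instances and checks
the output against a brute-force oracle each time.

```{r mine-example}
ag <- example_attributed_graph()
mine_maximal_cohesive(ag, 2, trace = TRUE)$trace
```

## Parameters that matter

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `s_min` | `mining_config()` | — | minimum shared dimensions (integer, $0 \le s_{\min} \le d$); `0` degenerates to connected components |
| `prune_*` | `mining_config()` | `TRUE` | the three prunes above; results are identical with any subset disabled |
| `max_sets` | `enumerate_cis()` etc. | unlimited | stop after so many sets; the stream is deterministic, so this is a reproducible head |
| `density` | `er_graph()` | — | independent edge probability |
| `background_rate` | `planted_model()` | `0.1` | probability a background attribute bit is 1 |

## What the synthetic generator emulates

`er_graph(n, density, seed)` draws an Erdős–Rényi graph: every unordered
pair is an edge independently. `planted_attributed_graph()` adds planted
modules: disjoint random vertex sets connected by a random spanning tree
(so each module is connected by construction), whose members share a
module-specific set of attribute dimensions, on top of i.i.d. background
bits. A single seed drives two derived sub-streams — topology and
attributes — so changing the noise rate never perturbs the topology.
Modules draw disjoint shared dimensions while $d$ allows, which keeps two
planted modules from merging into one cohesive superset; at
`background_rate = 0` the planted modules are then *exactly* the maximal
cohesive answer at $s_{\min}$ up to their shared-dimension count, which is
what the recovery tests assert (with noisy backgrounds they assert
containment instead, since background bits can legitimately extend a
module).

What the generator does **not** emulate: degree-corrected or scale-free
topologies, correlated attribute noise, and real interaction networks'
hub structure. Tests passing on these instances show algorithmic
correctness (exactness of the enumeration, soundness and completeness of
the pruning), not biological performance on real data.

## Numerical and design choices

* **Vertex order.** Ids follow the ascending sort of the distinct labels.
  Fully numeric label sets sort numerically — a file with vertices
  `1..14` keeps its natural order, which the bundled worked example
  depends on — otherwise the sort is plain C-locale lexicographic.
* **Degenerate inputs.** Self-loops and duplicate edges are dropped with a
  warning; disconnected graphs are fine (each component enumerates under
  its own roots); isolated vertices yield exactly their singleton set;
  `s_min > d` is rejected as a data error.
* **Determinism.** Identical inputs give byte-identical outputs everywhere
  (fixed child order, fixed root order, seeded generators), so golden-file
  comparisons are stable.
* **Guards.** The brute-force oracles refuse $n > 22$ (enumeration) and
  $n > 16$ (mining); they exist to check the fast path on small instances,
  not to be fast.
* **Problem sizes in the test-suite.** The property sweeps use 200 seeded
  random graphs ($n \in 4..12$, density $0.1..0.9$) for enumeration
  exactness and the parent–child inverse, 100 seeded planted instances
  ($n \le 12$, $d \le 6$) for mining correctness across all pruning-flag
  combinations, closed-form families up to size 20, and a dense $n = 20$
  full enumeration plus a streamed $n = 27$ head as scale smoke tests.

## Known limitations

* Attributes are binary; real-valued similarity constraints are out of
  scope.
* The miner retains all reported sets in memory (they are usually few);
  the plain enumerator streams.
* No parallelism: the traversal is a single DFS.
* The recursion depth equals the largest member count, so pathological
  inputs beyond $\sim 10^5$ vertices in one path would need a larger C
  stack.
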