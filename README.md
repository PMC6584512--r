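# cismine

Linear-delay enumeration of all connected induced subgraphs of an
undirected graph, and mining of all **maximal cohesive subgraphs** of a
binary vertex-attributed graph.

Module discovery in biological networks (protein–protein interaction
graphs annotated with per-condition dysregulation bits, for instance)
often reduces to walking the space of connected induced subgraphs and
keeping the ones whose vertices agree on enough attributes. `cismine`
provides that backbone:

* a reverse-search enumerator: every connected vertex set $U$ of
  $G=(V,E)$ is emitted exactly once, with delay linear in $|V|$ and
  auxiliary memory linear in $|V|$, so arbitrarily large solution streams
  never have to be materialized. The search tree is defined by a *parent*
  operation that deletes the *utmost* vertex — the member farthest (in
  shortest-path distance inside $G(U)$) from the minimum-id member (the
  *anchor*), ties to the larger id — and its inverse child rule
  $v > s$ and $(\mathrm{dist}(s,v), v) > (\mathrm{dist}(s,u), u)$;
* a miner for maximal cohesive subgraphs of $G=(V,E,f)$,
  $f: V \to \{0,1\}^d$: connected sets whose members share at least
  $S_{\min}$ attribute dimensions and that admit no cohesive connected
  strict superset, with three anti-monotone prunes (covering siblings,
  dominated level-one roots, parent-identical children) that cut the
  search tree without changing the answer;
* plain-text I/O (edge lists, two attribute-table dialects), seeded
  Erdős–Rényi and planted-module generators, brute-force oracles for
  testing, and a command-line interface.

## Worked example

The bundled 14-vertex, 22-edge graph realizes the distance-array state
discussed in the documentation of `enum_state_new()`:

```r
library(cismine)
g  <- example_graph_14()
U  <- c(2, 3, 4, 5, 7, 9)
anchor_vertex(U)      # 2
utmost_vertex(g, U)   # 9
st <- enum_state_for(g, U)
st
#> reverse-search state
#>   U: 2 3 5 4 7 9
#>   C: 10 8 14
#>   D: 2=0 3=1 4=2 5=1 6=2 7=3 8=4 9=3 10=3 14=4
#>   P: 3<-2 4<-3 5<-2 6<-3 7<-4 8<-7 9<-4 10<-4 14<-9
st$D[utmost_vertex(g, U)]  # 3: the utmost vertex sits 3 hops from the anchor
state_extend(st, 10)       # vertex 10 becomes the utmost vertex
st$D[c(11, 12)]            # 4 4  -- the two admitted candidates
st$P[c(11, 12)]            # 10 10
state_backtrack(st)        # restores the previous state bit-exactly
```

Counting and streaming:

```r
count_cis(cis_graph(cbind(c("a","b"), c("b","c"))))  # 6 sets on a 3-path
count_cis(family_graph("path", 10000))               # 50005000, a few seconds
enumerate_cis(er_graph(27, 0.6, 1), max_sets = 100)  # first 100 sets only
```

Mining the bundled attributed example at $S_{\min} = 2$:

```r
ag <- example_attributed_graph()
mine_maximal_cohesive(ag, 2)
#> 2 maximal cohesive subgraph(s) at s_min = 2
#>   {A,B,F,G,H} | f1,f2
#>   {A,B,C,G,H} | f2,f3
```

Two maximal modules: `A,B,F,G,H` jointly carry features `f1,f2` and
`A,B,C,G,H` carry `f2,f3`; no cohesive connected superset of either
exists. With `trace = TRUE` the result records every pruning event
(level-one root prunes, covered siblings, parent-identical cutoffs).

## Command line

```sh
inst/cli/cismine count graph.edges           # one integer on stdout
inst/cli/cismine enumerate graph.edges --out sets.tsv
inst/cli/cismine mine graph.edges --attributes graph.attrs --smin 3
inst/cli/cismine simulate --n 50 --density 0.1 --d 8 --modules 6:4,5:3 \
    --seed 7 --out sim            # sim.edges, sim.attrs, sim.yaml
```

Diagnostics go to stderr; exit status is 0 on success, 1 on data errors,
2 on usage errors.

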