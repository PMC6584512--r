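# Union-find connectivity over the subgraph induced by `members`.  The
# oracle deliberately shares no traversal code with the enumeration
# engine (C++ state machine) or the BFS helpers; a test cross-checks it
# against igraph as a second independent implementation.
oracle_connected <- function(graph, members) {
  members <- as.integer(members)
  k <- length(members)
  if (k == 0) return(FALSE)
  if (k == 1) return(TRUE)
  pos <- rep(NA_integer_, graph$n)
  pos[members] <- seq_len(k)
  parent <- seq_len(k)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (v in members) {
    for (w in graph$adj[[v]]) {
      if (w > v && !is.na(pos[w])) {
        a <- find(pos[v])
        b <- find(pos[w])
        if (a != b) parent[a] <- b
      }
    }
  }
  root <- find(1L)
  all(vapply(seq_len(k), find, integer(1)) == root)
}

#' Brute-force enumeration of connected vertex sets
#'
#' The naive reference: walk the whole power set and keep the subsets that
#' induce a connected subgraph (union-find connectivity).  Exponential by
#' construction; guarded to small graphs and used only as a test oracle.
#'
#' @param graph a [cis_graph()] with at most 22 vertices.
#' @return List with `sets` (sorted integer id vectors, in mask order) and
#'   `count`.
#' @export
brute_force_cis <- function(graph) {
  if (graph$n > 22) stop("brute-force oracle is limited to n <= 22")
  n <- graph$n
  bits <- 2^(seq_len(n) - 1)
  sets <- list()
  for (mask in seq_len(2^n - 1)) {
    members <- which(bitwAnd(mask, bits) != 0)
    if (oracle_connected(graph, members))
      sets[[length(sets) + 1]] <- members
  }
  list(sets = sets, count = length(sets))
}

#' Brute-force enumeration of maximal cohesive subgraphs
#'
#' Filters the brute-force connected sets to the cohesive ones (at least
#' `s_min` shared dimensions) and keeps those with no cohesive
#' single-vertex extension — equivalent to having no cohesive connected
#' strict superset, since any such superset is reachable one adjacent
#' vertex at a time and cohesion is anti-monotone.
#'
#' @param agraph a [cis_attributed_graph()] on at most 16 vertices.
#' @param s_min cohesion threshold.
#' @return List with `sets` (sorted integer id vectors) and `count`.
#' @export
brute_force_maximal_cohesive <- function(agraph, s_min) {
  graph <- agraph$graph
  if (graph$n > 16) stop("brute-force oracle is limited to n <= 16")
  feat <- agraph$features == 1L
  connected <- brute_force_cis(graph)$sets
  keep <- list()
  for (members in connected) {
    sig <- apply(feat[members, , drop = FALSE], 2, all)
    if (sum(sig) < s_min) next
    nbrs <- setdiff(unique(unlist(graph$adj[members])), members)
    extendable <- FALSE
    for (w in nbrs) {
      if (sum(sig & feat[w, ]) >= s_min) {
        extendable <- TRUE
        break
      }
    }
    if (!extendable) keep[[length(keep) + 1]] <- members
  }
  list(sets = keep, count = length(keep))
}

#' Closed-form counts of connected vertex sets for standard families
#'
#' Path `P_n`: the non-empty contiguous intervals, `n(n+1)/2`.  Complete
#' `K_n`: every non-empty subset, `2^n - 1`.  Star with `k` leaves: any
#' leaf subset plus the center, or a single leaf, `2^k + k`.  Cycle `C_n`:
#' the `n(n-1)` proper arcs plus the full cycle, `n(n-1) + 1`.
#'
#' @param family one of `"path"`, `"complete"`, `"star"`, `"cycle"`.
#' @param size path/complete/cycle: vertex count; star: number of leaves.
#' @return The count as a double.
#' @export
closed_form_count <- function(family = c("path", "complete", "star", "cycle"),
                              size) {
  family <- match.arg(family)
  size <- as.integer(size)
  if (is.na(size) || size < 1) stop("size must be a positive integer")
  if (family == "cycle" && size < 3) stop("a cycle needs at least 3 vertices")
  switch(family,
         path = size * (size + 1) / 2,
         complete = 2^size - 1,
         star = 2^size + size,
         cycle = size * (size - 1) + 1)
}
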