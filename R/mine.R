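#' Mining configuration
#'
#' @param s_min minimum number of cohesive dimensions a reported subgraph
#'   must share (integer >= 0).
#' @param prune_covering_sibling drop a candidate branch whose signature is
#'   contained in a preceding sibling's signature.
#' @param prune_same_as_parent after recursing into a child whose signature
#'   equals its parent's, skip all later siblings.
#' @param prune_level_one skip a root vertex dominated by a smaller
#'   neighbor with a superset of its features.
#' @return A list of class `mining_config`.
#' @export
mining_config <- function(s_min,
                          prune_covering_sibling = TRUE,
                          prune_same_as_parent = TRUE,
                          prune_level_one = TRUE) {
  s_min <- as.integer(s_min)
  if (is.na(s_min) || s_min < 0) stop("s_min must be a non-negative integer")
  structure(list(s_min = s_min,
                 prune_covering_sibling = isTRUE(prune_covering_sibling),
                 prune_same_as_parent = isTRUE(prune_same_as_parent),
                 prune_level_one = isTRUE(prune_level_one)),
            class = "mining_config")
}

#' Cohesive feature signature of a vertex set
#'
#' Dimension `j` is cohesive for `U` when every member carries feature
#' `j`; the signature is the bitwise AND of the members' feature vectors.
#' The empty set's signature is all ones, so signatures only ever shrink
#' along a root-to-node path (the anti-monotone property the pruning
#' rules rely on).
#'
#' @param agraph a [cis_attributed_graph()].
#' @param U integer vector of vertex ids (may be empty).
#' @return Named logical vector of length `d`.
#' @export
feature_signature <- function(agraph, U) {
  U <- as.integer(U)
  if (length(U) && (min(U) < 1 || max(U) > agraph$graph$n))
    stop("vertex id out of range")
  sig <- rep(TRUE, agraph$d)
  for (v in U) sig <- sig & (agraph$features[v, ] == 1L)
  names(sig) <- agraph$feature_names
  sig
}

#' Cohesion test
#'
#' @param sig logical signature as returned by [feature_signature()].
#' @param s_min threshold, or a [mining_config()].
#' @return `TRUE` iff the signature keeps at least `s_min` dimensions.
#' @export
is_cohesive <- function(sig, s_min) {
  if (inherits(s_min, "mining_config")) s_min <- s_min$s_min
  sum(sig) >= s_min
}

#' Candidate order used by the miner
#'
#' Sorts candidates by closeness to the anchor — ascending (distance, id)
#' key, the same total order the child-validity rule uses — so that
#' "preceding sibling" is well defined for the covering prune.
#'
#' @param state a [enum_state_new()] state.
#' @param candidates vertex ids that are live candidates of the state.
#' @return The candidates, reordered.
#' @export
order_candidates <- function(state, candidates) {
  candidates <- as.integer(candidates)
  candidates[order(state$D[candidates], candidates)]
}

#' Covering-sibling prune
#'
#' Walking the ordered candidates, a candidate `y` is dropped when some
#' earlier kept candidate `x` satisfies
#' `sig(U + y) <= sig(U + x)` elementwise: every maximal superset of
#' `U + y` would also contain `x`, and is reachable through the `x`
#' branch.  Ties (equal signatures) keep the earlier candidate.
#'
#' @param agraph a [cis_attributed_graph()].
#' @param parent_sig signature of the current node.
#' @param ordered candidates in [order_candidates()] order, all cohesive.
#' @return Logical keep flags aligned with `ordered`.
#' @export
prune_covered_siblings <- function(agraph, parent_sig, ordered) {
  sigs <- lapply(ordered, function(v)
    parent_sig & (agraph$features[v, ] == 1L))
  keep <- logical(length(ordered))
  kept <- list()
  for (i in seq_along(ordered)) {
    covered <- any(vapply(kept, function(s) all(sigs[[i]] <= s), logical(1)))
    keep[i] <- !covered
    if (!covered) kept[[length(kept) + 1]] <- sigs[[i]]
  }
  keep
}

#' Level-one (root) prune test
#'
#' A root vertex `v` is skipped when a smaller neighbor `w` carries a
#' superset of `v`'s features: every cohesive set grown from `v` alone
#' stays cohesive after adding `w`, so none of the sets under root `v` can
#' be maximal, and the sets containing `w` are enumerated under a smaller
#' root.
#'
#' @param agraph a [cis_attributed_graph()].
#' @param v vertex id.
#' @return `TRUE` when the root is kept.
#' @export
level_one_keep <- function(agraph, v) {
  v <- as.integer(v)
  fv <- agraph$features[v, ] == 1L
  for (w in agraph$graph$adj[[v]]) {
    if (w < v && all(fv <= (agraph$features[w, ] == 1L))) return(FALSE)
  }
  TRUE
}

#' Parent-identical signature cutoff
#'
#' When a child keeps its parent's full signature, every later sibling's
#' branch is covered by this child's branch, so the miner recurses into
#' the child and skips the remaining siblings without further covering
#' checks.
#'
#' @param parent_sig,child_sig logical signatures.
#' @return `TRUE` iff the signatures are identical.
#' @export
same_as_parent_cutoff <- function(parent_sig, child_sig) {
  all(parent_sig == child_sig)
}

#' Maximality test for a cohesive connected set
#'
#' `U` is maximal iff no graph neighbor — valid candidate, invalidated
#' candidate, pruned vertex, or vertex below the anchor — keeps at least
#' `s_min` cohesive dimensions when added.  Single-vertex extensions
#' suffice: any connected cohesive strict superset contains such a
#' neighbor, and adding it alone preserves cohesion by anti-monotonicity.
#'
#' @param agraph a [cis_attributed_graph()].
#' @param U integer ids of a connected cohesive set.
#' @param s_min threshold, or a [mining_config()].
#' @return `TRUE` or `FALSE`.
#' @export
is_maximal <- function(agraph, U, s_min) {
  if (inherits(s_min, "mining_config")) s_min <- s_min$s_min
  U <- as.integer(U)
  sig <- feature_signature(agraph, U)
  nbrs <- setdiff(unique(unlist(agraph$graph$adj[U])), U)
  for (w in nbrs) {
    if (sum(sig & (agraph$features[w, ] == 1L)) >= s_min) return(FALSE)
  }
  TRUE
}

#' Mine all maximal cohesive subgraphs
#'
#' Depth-first traversal of the reverse-search tree restricted to cohesive
#' nodes.  At each node the cohesive valid candidates are sorted by
#' closeness to the anchor, covered siblings are dropped, and a child that
#' keeps its parent's signature cuts off its remaining siblings; a node is
#' reported iff no single-vertex extension stays cohesive.  With all
#' pruning disabled the result is identical, only slower.
#'
#' @param agraph a [cis_attributed_graph()].
#' @param config a [mining_config()], or an integer taken as `s_min` with
#'   all pruning enabled.
#' @param trace record traversal events (root prunes, covered siblings,
#'   parent-identical cutoffs, reports) in a data frame.
#' @return An object of class `cohesive_sets`: list with `sets` (integer
#'   id vectors, ascending), `dims` (cohesive dimension indices per set),
#'   `labels`, `feature_names`, `nodes_visited` and (when requested)
#'   `trace`.
#' @examples
#' ag <- example_attributed_graph()
#' mine_maximal_cohesive(ag, 2)
#' @export
mine_maximal_cohesive <- function(agraph, config, trace = FALSE) {
  if (!inherits(config, "mining_config")) config <- mining_config(config)
  if (config$s_min > agraph$d)
    stop("S_min exceeds attribute dimension")
  res <- cpp_mine(agraph$graph$adj, agraph$features, agraph$graph$labels,
                  config$s_min,
                  config$prune_covering_sibling,
                  config$prune_same_as_parent,
                  config$prune_level_one,
                  isTRUE(trace))
  out <- list(sets = res$sets, dims = res$dims,
              labels = agraph$graph$labels,
              feature_names = agraph$feature_names,
              s_min = config$s_min,
              nodes_visited = res$nodes_visited)
  if (isTRUE(trace))
    out$trace <- data.frame(event = res$trace$event, node = res$trace$node,
                            vertex = res$trace$vertex, by = res$trace$by,
                            stringsAsFactors = FALSE)
  class(out) <- "cohesive_sets"
  out
}

#' @export
print.cohesive_sets <- function(x, n = 10, ...) {
  cat(sprintf("%d maximal cohesive subgraph(s) at s_min = %d\n",
              length(x$sets), x$s_min))
  for (i in seq_len(min(n, length(x$sets)))) {
    cat(sprintf("  {%s} | %s\n",
                paste(x$labels[x$sets[[i]]], collapse = ","),
                paste(x$feature_names[x$dims[[i]]], collapse = ",")))
  }
  if (length(x$sets) > n) cat(sprintf("  ... and %d more\n",
                                      length(x$sets) - n))
  invisible(x)
}

#' Write mined subgraphs, one per line
#'
#' Member labels in ascending id order joined by tabs, then a `|` column,
#' then the sorted cohesive feature names joined by commas.
#'
#' @param result a `cohesive_sets` object.
#' @param sink file path or connection.
#' @return Number of lines written.
#' @export
write_cohesive_sets <- function(result, sink) {
  lines <- vapply(seq_along(result$sets), function(i) {
    feats <- sort(result$feature_names[result$dims[[i]]], method = "radix")
    paste0(paste(result$labels[result$sets[[i]]], collapse = "\t"),
           "\t|\t", paste(feats, collapse = ","))
  }, character(1))
  writeLines(lines, sink)
  length(lines)
}
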