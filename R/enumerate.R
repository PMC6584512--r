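#' Enumerate all connected induced subgraphs
#'
#' Depth-first reverse-search enumeration: every connected vertex set is
#' visited exactly once, under the root equal to its minimum id, children
#' in candidate-array order, sets emitted pre-order.  Delay between
#' consecutive sets is linear in the graph size and the auxiliary state is
#' a fixed number of length-`n` arrays, so arbitrarily large outputs can
#' be streamed.
#'
#' @param graph a [cis_graph()].
#' @param visitor optional function called once per set with the sorted
#'   integer ids.  With a visitor the return value is the total count;
#'   without one all sets are materialized and returned (intended for
#'   small graphs: the number of sets can grow exponentially).
#' @param max_sets stop after this many sets (default unlimited); useful
#'   for streaming the head of a huge enumeration.
#' @return Total count (with a visitor), or a list of sorted integer id
#'   vectors with the count in attribute `count`.
#' @examples
#' g <- cis_graph(cbind(c("a", "b"), c("b", "c")))
#' count_cis(g)                      # 6 sets on a 3-path
#' enumerate_cis(g)
#' @export
enumerate_cis <- function(graph, visitor = NULL, max_sets = Inf) {
  lim <- if (is.finite(max_sets)) as.double(max_sets) else -1
  if (!is.null(visitor)) {
    cpp_visit_cis(graph$adj, visitor, lim)
  } else {
    sets <- cpp_collect_cis(graph$adj, lim)
    attr(sets, "count") <- length(sets)
    sets
  }
}

#' Count connected induced subgraphs
#'
#' Same traversal as [enumerate_cis()] with a counting visitor and no
#' materialization; memory stays linear in the vertex count regardless of
#' how many sets exist.
#'
#' @inheritParams enumerate_cis
#' @return The number of connected vertex sets (as a double; counts can
#'   exceed the integer range).
#' @export
count_cis <- function(graph, max_sets = Inf) {
  lim <- if (is.finite(max_sets)) as.double(max_sets) else -1
  cpp_count_cis(graph$adj, lim)
}

#' Stream connected induced subgraphs to a file
#'
#' Writes one set per line in the [write_vertex_sets()] format (labels,
#' ascending id order, tab-separated) directly from the enumeration
#' engine.
#'
#' @inheritParams enumerate_cis
#' @param path output file path.
#' @return Number of sets written.
#' @export
write_cis <- function(graph, path, max_sets = Inf) {
  lim <- if (is.finite(max_sets)) as.double(max_sets) else -1
  cpp_write_cis(graph$adj, graph$labels, path, lim)
}
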