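# Breadth-first distances from `from` inside the subgraph induced by
# `members`.  Deliberately independent of the enumeration state machinery:
# it is the reference used to verify it.
bfs_distances <- function(graph, members, from) {
  members <- as.integer(members)
  dist <- rep(NA_integer_, graph$n)
  dist[from] <- 0L
  queue <- from
  inset <- logical(graph$n)
  inset[members] <- TRUE
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    for (w in graph$adj[[v]]) {
      if (inset[w] && is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  dist[members]
}

#' Anchor of a vertex set
#'
#' The anchor is the smallest-id vertex of the set; distances and the
#' utmost vertex are defined relative to it.
#'
#' @param U non-empty integer vector of vertex ids.
#' @return A vertex id.
#' @export
anchor_vertex <- function(U) {
  if (length(U) == 0) stop("anchor of an empty set is undefined")
  min(as.integer(U))
}

#' Utmost vertex of a connected vertex set
#'
#' The member with the longest shortest-path distance to the anchor inside
#' the induced subgraph; ties go to the largest id.  Deleting the utmost
#' vertex always leaves the induced subgraph connected, which is what
#' makes [parent_of()] well defined.
#'
#' @param graph a [cis_graph()].
#' @param U non-empty integer vector of vertex ids inducing a connected
#'   subgraph.
#' @return A vertex id.
#' @export
utmost_vertex <- function(graph, U) {
  U <- sort(as.integer(U))
  dist <- bfs_distances(graph, U, anchor_vertex(U))
  if (anyNA(dist)) stop("vertex set does not induce a connected subgraph")
  far <- U[dist == max(dist)]
  max(far)
}

#' Parent of a connected vertex set in the reverse-search tree
#'
#' Deletes the utmost vertex.  Applied repeatedly, any connected set
#' reduces to the empty set, the canonical root of the search tree.
#'
#' @inheritParams utmost_vertex
#' @return An integer vector with one member fewer (possibly empty).
#' @export
parent_of <- function(graph, U) {
  U <- sort(as.integer(U))
  setdiff(U, utmost_vertex(graph, U))
}

#' Create the enumeration state for a single-vertex root
#'
#' The state mirrors the distance-array representation: member array `U`
#' (insertion order), candidate array `C` (`NA` marks the slot of an
#' extended or invalidated candidate), distance array `D` and parent array
#' `P` (`NA` for untouched vertices), plus a restoration stack.  Only
#' neighbors greater than the anchor are admitted to `C`; smaller vertices
#' can never satisfy the child-validity rule under this root.
#'
#' @param graph a [cis_graph()].
#' @param root vertex id of the root singleton.
#' @return An environment of class `cis_enum_state`.
#' @export
enum_state_new <- function(graph, root) {
  root <- as.integer(root)
  stopifnot(root >= 1, root <= graph$n)
  st <- new.env(parent = emptyenv())
  st$graph <- graph
  st$U <- root
  st$D <- rep(NA_integer_, graph$n)
  st$P <- rep(NA_integer_, graph$n)
  st$inU <- logical(graph$n)
  st$D[root] <- 0L
  st$inU[root] <- TRUE
  nb <- graph$adj[[root]]
  nb <- nb[nb > root]
  st$C <- nb
  st$D[nb] <- 1L
  st$P[nb] <- root
  st$frames <- list()
  class(st) <- "cis_enum_state"
  st
}

#' @export
print.cis_enum_state <- function(x, ...) {
  lab <- x$graph$labels
  cat("reverse-search state\n")
  cat("  U:", paste(lab[x$U], collapse = " "), "\n")
  live <- x$C[!is.na(x$C)]
  cat("  C:", paste(lab[live], collapse = " "), "\n")
  touched <- which(!is.na(x$D))
  cat("  D:", paste(sprintf("%s=%d", lab[touched], x$D[touched]),
                    collapse = " "), "\n")
  withp <- which(!is.na(x$P))
  cat("  P:", paste(sprintf("%s<-%s", lab[withp], lab[x$P[withp]]),
                    collapse = " "), "\n")
  invisible(x)
}

#' Members, candidates and array snapshot of an enumeration state
#'
#' `state_members()` returns the member array in insertion order (the last
#' element is the utmost vertex); `state_candidates()` the live candidate
#' array in slot order; `state_snapshot()` the full `U`/`C`/`D`/`P` arrays
#' for bit-exact comparison across extend/backtrack cycles.
#'
#' @param state a [enum_state_new()] state.
#' @return Integer vector, or a named list of the four arrays.
#' @export
state_members <- function(state) state$U

#' @rdname state_members
#' @export
state_candidates <- function(state) state$C[!is.na(state$C)]

#' @rdname state_members
#' @export
state_snapshot <- function(state)
  list(U = state$U, C = state$C, D = state$D, P = state$P)

# (distance, id) child-order key comparison
key_before <- function(state, x, v) {
  state$D[x] < state$D[v] || (state$D[x] == state$D[v] && x < v)
}

#' Child-validity test
#'
#' A candidate `v` extends the current set to a child of the search node
#' iff `v` is greater than the anchor and its (distance, id) key exceeds
#' the utmost vertex's key: farther from the anchor, or equally far with a
#' larger id.
#'
#' @param state a [enum_state_new()] state.
#' @param v a vertex id adjacent to the current member set.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_child <- function(state, v) {
  v <- as.integer(v)
  if (state$inU[v]) stop("vertex is already a member of U")
  anchor <- state$U[[1]]
  if (v <= anchor) return(FALSE)
  if (is.na(state$D[v]))
    stop("vertex has no assigned distance (not a touched neighbor of U)")
  u <- state$U[[length(state$U)]]
  state$D[v] > state$D[u] || (state$D[v] == state$D[u] && v > u)
}

#' Extend the state with a valid candidate
#'
#' Appends `v` to `U` (it becomes the utmost vertex), admits every
#' untouched neighbor of `v` above the anchor into `C` with distance
#' `D[v] + 1` and parent `v`, and moves every remaining candidate whose
#' (distance, id) key precedes `v`'s onto the restoration stack: with the
#' utmost key only ever growing inside this subtree, such candidates can
#' never pass the validity test again until backtracking.
#'
#' @param state a [enum_state_new()] state; modified in place.
#' @param v a live candidate id; must satisfy [is_valid_child()].
#' @return The state, invisibly.
#' @export
state_extend <- function(state, v) {
  v <- as.integer(v)
  slot <- match(v, state$C)
  if (is.na(slot)) stop("vertex is not a live candidate")
  if (!is_valid_child(state, v)) stop("vertex is not a valid child")
  state$C[slot] <- NA_integer_
  live <- which(!is.na(state$C))
  inv <- live[vapply(state$C[live], key_before, logical(1), state = state,
                     v = v)]
  frame <- list(v = v, slot = slot, inv_v = state$C[inv], inv_slot = inv,
                add_base = length(state$C))
  state$C[inv] <- NA_integer_
  state$U <- c(state$U, v)
  state$inU[v] <- TRUE
  anchor <- state$U[[1]]
  new <- graph_neighbors(state$graph, v)
  new <- new[new > anchor & is.na(state$D[new])]
  state$D[new] <- state$D[v] + 1L
  state$P[new] <- v
  state$C <- c(state$C, new)
  state$frames[[length(state$frames) + 1]] <- frame
  invisible(state)
}

graph_neighbors <- function(graph, v) graph$adj[[v]]

#' Undo the most recent extension
#'
#' Exact inverse of [state_extend()]: candidates admitted by the removed
#' vertex are dropped and their `D`/`P` entries reset, invalidated
#' candidates return to their original slots, and the removed vertex
#' returns to its candidate slot.  The state is bit-identical to what it
#' was before the matching extension.
#'
#' @param state a [enum_state_new()] state; modified in place.
#' @return The state, invisibly.
#' @export
state_backtrack <- function(state) {
  k <- length(state$frames)
  if (k == 0) stop("nothing to backtrack: state is at its root")
  frame <- state$frames[[k]]
  state$frames[[k]] <- NULL
  added <- state$C[seq_len(length(state$C) - frame$add_base) + frame$add_base]
  state$D[added] <- NA_integer_
  state$P[added] <- NA_integer_
  state$C <- state$C[seq_len(frame$add_base)]
  state$C[frame$inv_slot] <- frame$inv_v
  state$U <- state$U[-length(state$U)]
  state$inU[frame$v] <- FALSE
  state$C[frame$slot] <- frame$v
  invisible(state)
}

#' Drive a fresh state to a given connected vertex set
#'
#' Rebuilds the unique root-to-node path of the reverse-search tree (the
#' reversed sequence of [parent_of()] reductions) and replays it with
#' [state_extend()].
#'
#' @param graph a [cis_graph()].
#' @param members integer ids of a connected vertex set.
#' @return A [enum_state_new()] state positioned at that search node.
#' @export
enum_state_for <- function(graph, members) {
  members <- sort(as.integer(members))
  order <- integer()
  S <- members
  while (length(S) > 1) {
    u <- utmost_vertex(graph, S)
    order <- c(u, order)
    S <- setdiff(S, u)
  }
  st <- enum_state_new(graph, S)
  for (v in order) state_extend(st, v)
  st
}

# Full pre-order DFS over the reverse-search tree using the R state
# machine.  node_fn (if given) is called at every search node with the
# live state.  Returns the number of nodes (= connected vertex sets).
# Small-graph reference driver; the compiled engine does the heavy work.
walk_cis <- function(graph, node_fn = NULL) {
  count <- 0
  rec <- function(st) {
    L <- length(st$C)
    for (i in seq_len(L)) {
      v <- st$C[[i]]
      if (is.na(v)) next
      state_extend(st, v)
      count <<- count + 1
      if (!is.null(node_fn)) node_fn(st)
      rec(st)
      state_backtrack(st)
    }
  }
  for (r in seq_len(graph$n)) {
    st <- enum_state_new(graph, r)
    count <- count + 1
    if (!is.null(node_fn)) node_fn(st)
    rec(st)
  }
  count
}
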