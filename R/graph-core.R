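#' @useDynLib cismine, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Total vertex order shared by every module: ids 1..n follow the ascending
# sort of the distinct labels.  Purely numeric label sets sort numerically
# (so "10" > "9", as in vertex-numbered graphs); anything else sorts in the
# C locale.
sort_labels <- function(labels) {
  labels <- unique(labels)
  num <- suppressWarnings(as.numeric(labels))
  if (!anyNA(num)) labels[order(num)] else sort(labels, method = "radix")
}

#' Build an undirected simple graph from an edge table
#'
#' Vertices receive dense integer ids `1..n` in ascending label order, the
#' total order used by the anchor/utmost child rule.  Self-loops and
#' duplicate edges (in either orientation) are dropped with a warning.
#'
#' @param edges two-column character matrix or data frame of endpoint
#'   labels; may have zero rows.
#' @param vertices extra vertex labels to include even if they touch no
#'   edge (isolated vertices are enumerated as singletons).
#' @return An object of class `cis_graph`: a list with `n` (vertex count),
#'   `labels` (original labels indexed by id), `adj` (per-vertex strictly
#'   increasing integer neighbor ids) and `m` (edge count).
#' @examples
#' g <- cis_graph(cbind(c("a", "b"), c("b", "c")))
#' g$n
#' @export
cis_graph <- function(edges, vertices = character()) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0) edges <- matrix(character(), ncol = 2)
  storage.mode(edges) <- "character"
  if (ncol(edges) < 2) stop("edge table needs two endpoint columns")
  edges <- edges[, 1:2, drop = FALSE]

  loops <- edges[, 1] == edges[, 2]
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  labels <- sort_labels(c(as.vector(edges), vertices))
  if (length(labels) == 0) stop("no edges or vertices")
  n <- length(labels)

  i <- match(edges[, 1], labels)
  j <- match(edges[, 2], labels)
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  key <- (lo - 1) * n + hi
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("dropped %d duplicate edge(s)", sum(dup)))
    lo <- lo[!dup]
    hi <- hi[!dup]
  }
  adj <- rep(list(integer()), n)
  if (length(lo)) {
    half <- data.frame(a = c(lo, hi), b = c(hi, lo))
    sp <- split(half$b, factor(half$a, levels = seq_len(n)))
    adj <- lapply(sp, function(x) sort(unique(as.integer(x))))
    names(adj) <- NULL
  }
  structure(list(n = n, labels = labels, adj = adj, m = length(lo)),
            class = "cis_graph")
}

#' @export
print.cis_graph <- function(x, ...) {
  cat(sprintf("cis_graph: %d vertices, %d edges (max degree %d)\n",
              x$n, x$m, if (x$n) max(lengths(x$adj)) else 0L))
  invisible(x)
}

#' Read an undirected graph from a whitespace-separated edge list
#'
#' One edge per line: two endpoint labels separated by whitespace; extra
#' columns are ignored.  Lines starting with `#` are comments, except for
#' an optional `# vertices: a b c` header that declares isolated vertices.
#'
#' @param source file path or connection.
#' @return A [cis_graph()].
#' @export
read_edge_list <- function(source) {
  lines <- readLines(source)
  vertices <- character()
  from <- character()
  to <- character()
  for (k in seq_along(lines)) {
    ln <- trimws(lines[[k]])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      body <- sub("^#\\s*", "", ln)
      if (grepl("^vertices:", body)) {
        vertices <- c(vertices,
                      strsplit(trimws(sub("^vertices:", "", body)),
                               "\\s+")[[1]])
      }
      next
    }
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) < 2)
      stop(sprintf("line %d: expected at least two vertex labels", k))
    from <- c(from, tok[[1]])
    to <- c(to, tok[[2]])
  }
  if (length(from) == 0 && length(vertices) == 0)
    stop("no edges or vertices")
  cis_graph(cbind(from, to), vertices = vertices)
}

#' Write a graph as an edge list
#'
#' One edge per line in ascending `(id, id)` order; isolated vertices go
#' into a `# vertices:` header so a round trip reproduces the graph.
#'
#' @param graph a [cis_graph()].
#' @param sink file path or connection.
#' @return Number of edge lines written, invisibly.
#' @export
write_edge_list <- function(graph, sink) {
  isolated <- graph$labels[lengths(graph$adj) == 0]
  lines <- character()
  if (length(isolated))
    lines <- paste("# vertices:", paste(isolated, collapse = " "))
  for (i in seq_len(graph$n)) {
    nb <- graph$adj[[i]]
    nb <- nb[nb > i]
    if (length(nb))
      lines <- c(lines, paste(graph$labels[i], graph$labels[nb], sep = "\t"))
  }
  writeLines(lines, sink)
  invisible(graph$m)
}

#' Attach binary vertex attributes to a graph
#'
#' @param graph a [cis_graph()].
#' @param features 0/1 matrix with one row per vertex in id order (or with
#'   rownames giving labels); column names become the feature names.
#' @return An object of class `cis_attributed_graph` with fields `graph`,
#'   `d`, `features` (integer 0/1 matrix, rows in id order) and
#'   `feature_names`.
#' @export
cis_attributed_graph <- function(graph, features) {
  features <- as.matrix(features)
  if (nrow(features) != graph$n)
    stop("features must have one row per vertex")
  if (ncol(features) < 1) stop("attribute dimension d must be >= 1")
  if (!all(features %in% c(0, 1))) stop("features must be binary (0/1)")
  if (!is.null(rownames(features))) {
    miss <- setdiff(graph$labels, rownames(features))
    if (length(miss))
      stop(sprintf("vertex '%s' missing from the attribute table", miss[[1]]))
    features <- features[graph$labels, , drop = FALSE]
  }
  storage.mode(features) <- "integer"
  if (is.null(colnames(features)))
    colnames(features) <- as.character(seq_len(ncol(features)))
  rownames(features) <- graph$labels
  structure(list(graph = graph, d = ncol(features), features = features,
                 feature_names = colnames(features)),
            class = "cis_attributed_graph")
}

#' @export
print.cis_attributed_graph <- function(x, ...) {
  cat(sprintf("cis_attributed_graph: %d vertices, %d edges, %d binary dimensions\n",
              x$graph$n, x$graph$m, x$d))
  invisible(x)
}

#' Read a vertex attribute table
#'
#' Two dialects, auto-detected from the first data row: *binary matrix*
#' (label followed by d whitespace-separated 0/1 values) or *feature list*
#' (label followed by a comma-separated list of feature names; a bare
#' label means no features).  In the feature-list dialect the dimensions
#' are the distinct feature names in ascending sorted order.
#'
#' @param source file path or connection.
#' @param graph the [cis_graph()] the attributes belong to; every vertex
#'   label must appear exactly once.
#' @return A [cis_attributed_graph()].
#' @export
read_attributes <- function(source, graph) {
  lines <- readLines(source)
  rows <- list()
  for (k in seq_along(lines)) {
    ln <- trimws(lines[[k]])
    if (ln == "" || startsWith(ln, "#")) next
    rows[[length(rows) + 1]] <- strsplit(ln, "\\s+")[[1]]
  }
  if (length(rows) == 0) stop("empty attribute table")
  labs <- vapply(rows, `[[`, character(1), 1)
  if (anyDuplicated(labs))
    stop(sprintf("vertex '%s' appears more than once in the attribute table",
                 labs[duplicated(labs)][[1]]))
  unknown <- setdiff(labs, graph$labels)
  if (length(unknown))
    stop(sprintf("attribute table row for unknown vertex '%s'", unknown[[1]]))
  miss <- setdiff(graph$labels, labs)
  if (length(miss))
    stop(sprintf("vertex '%s' missing from the attribute table", miss[[1]]))

  first <- rows[[1]]
  matrix_dialect <- length(first) >= 2 && all(first[-1] %in% c("0", "1"))
  if (matrix_dialect) {
    d <- length(first) - 1
    feat <- matrix(0L, graph$n, d)
    for (r in rows) {
      if (length(r) - 1 != d)
        stop(sprintf("vertex '%s': expected %d attribute columns, found %d",
                     r[[1]], d, length(r) - 1))
      vals <- r[-1]
      if (!all(vals %in% c("0", "1")))
        stop(sprintf("vertex '%s': non-binary attribute value", r[[1]]))
      feat[match(r[[1]], graph$labels), ] <- as.integer(vals)
    }
    colnames(feat) <- as.character(seq_len(d))
  } else {
    sets <- lapply(rows, function(r) {
      if (length(r) < 2) return(character())
      unique(strsplit(paste(r[-1], collapse = ""), ",")[[1]])
    })
    fnames <- sort(unique(unlist(sets)), method = "radix")
    if (length(fnames) == 0) stop("attribute table defines no features")
    feat <- matrix(0L, graph$n, length(fnames), dimnames = list(NULL, fnames))
    for (i in seq_along(rows))
      feat[match(labs[[i]], graph$labels), match(sets[[i]], fnames)] <- 1L
  }
  cis_attributed_graph(graph, feat)
}

#' Write vertex sets, one per line
#'
#' Members are printed as their original labels in ascending id order,
#' joined by tabs.
#'
#' @param sets list of integer vertex-id vectors.
#' @param graph the [cis_graph()] providing the labels.
#' @param sink file path or connection.
#' @return Number of lines written.
#' @export
write_vertex_sets <- function(sets, graph, sink) {
  lines <- vapply(sets, function(s) {
    s <- sort(as.integer(s))
    if (length(s) && (min(s) < 1 || max(s) > graph$n))
      stop("vertex id out of range")
    paste(graph$labels[s], collapse = "\t")
  }, character(1))
  writeLines(lines, sink)
  length(lines)
}

# igraph view of a cis_graph; used by the BFS-backed set operations and as
# the second, independent connectivity implementation in tests.
cis_to_igraph <- function(graph) {
  g <- igraph::make_empty_graph(graph$n, directed = FALSE)
  el <- do.call(rbind, lapply(seq_len(graph$n), function(i) {
    nb <- graph$adj[[i]]
    nb <- nb[nb > i]
    if (length(nb)) cbind(i, nb) else NULL
  }))
  if (!is.null(el)) g <- igraph::add_edges(g, as.vector(t(el)))
  g
}
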