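#' The 14-vertex distance-array example graph
#'
#' A synthetic 14-vertex, 22-edge graph constructed so that the search
#' state for the connected set \{2,3,4,5,7,9\} reproduces the documented
#' distance-array worked example exactly: anchor 2, utmost 9 at distance 3,
#' parents 2-1, 2-3, 2-5, 3-4, 3-6, 4-7, 4-9, 4-10, 7-8, 9-14, and
#' extension with vertex 10 admitting candidates 11 and 12 at distance 4.
#' Vertex 13 is untouched by that state.
#'
#' @return A [cis_graph()] with numeric labels "1".."14".
#' @export
example_graph_14 <- function() {
  edges <- matrix(c(
    2, 1,   2, 3,   2, 5,   3, 4,   3, 6,
    4, 7,   4, 9,   4, 10,  7, 8,   9, 14,
    10, 11, 10, 12,
    4, 5,   7, 9,   5, 6,   6, 7,   8, 9,
    1, 6,   8, 14,  11, 12, 12, 13, 13, 14
  ), ncol = 2, byrow = TRUE)
  cis_graph(matrix(as.character(edges), ncol = 2))
}

#' The 6-vertex attributed example graph
#'
#' A synthetic node-attributed graph (vertices A, B, C, F, G, H over d = 6
#' binary dimensions) constructed so that mining maximal cohesive
#' subgraphs at `s_min = 2` exercises every pruning rule on record:
#' level-one pruning removes roots C and H, \{A,F\} is covered by the
#' preceding sibling \{A,B\}, \{A,B,C\} and \{A,B,G\} are covered by
#' \{A,B,H\}, and under \{A,B,F\} the child \{A,B,F,H\} keeps its parent's
#' signature and triggers the parent-identical cutoff.
#'
#' @return A [cis_attributed_graph()].
#' @export
example_attributed_graph <- function() {
  g <- cis_graph(cbind(c("A", "A", "A", "B", "B"),
                       c("B", "F", "H", "C", "G")))
  feat <- rbind(
    A = c(1, 1, 1, 1, 1, 0),
    B = c(1, 1, 1, 1, 0, 1),
    C = c(0, 1, 1, 0, 0, 1),
    F = c(1, 1, 0, 0, 0, 1),
    G = c(1, 1, 1, 0, 1, 0),
    H = c(1, 1, 1, 0, 0, 0)
  )
  colnames(feat) <- paste0("f", 1:6)
  cis_attributed_graph(g, feat)
}

#' Path to a bundled example file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
cismine_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "cismine")))
  path <- system.file("extdata", file, package = "cismine")
  if (path == "") stop(sprintf("no bundled example file '%s'", file))
  path
}
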