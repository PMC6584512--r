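# Canonical string form of a collection of vertex sets, for exact
# set-of-sets comparisons independent of emission order.
canon_sets <- function(sets) {
  sort(vapply(sets, function(s) paste(sort(as.integer(s)), collapse = ","),
              character(1)))
}

# Tiny literal graph from "a-b" edge strings.
graph_from_pairs <- function(pairs, vertices = character()) {
  parts <- strsplit(pairs, "-", fixed = TRUE)
  cis_graph(cbind(vapply(parts, `[[`, character(1), 1),
                  vapply(parts, `[[`, character(1), 2)),
            vertices = vertices)
}

# The 4-vertex sample graph used for the child-validity examples:
# A-B, A-D, B-C, B-D, C-D (distance(A,C) = 2, distance(A,D) = 1).
sample_graph_4 <- function() {
  graph_from_pairs(c("A-B", "A-D", "B-C", "B-D", "C-D"))
}

expect_same_sets <- function(got, want) {
  expect_identical(canon_sets(got), canon_sets(want))
}
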