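test_that("edge lists parse with sorted dense ids", {
  g <- read_edge_list(textConnection(c("a b", "b c")))
  expect_identical(g$labels, c("a", "b", "c"))
  expect_equal(g$n, 3)
  expect_equal(g$m, 2)
  expect_identical(g$adj, list(2L, c(1L, 3L), 2L))
})

test_that("self-loops and duplicate edges are dropped with a warning", {
  expect_warning(g <- read_edge_list(textConnection(c("x x", "x y"))),
                 "self-loop")
  expect_equal(g$n, 2)
  expect_equal(g$m, 1)
  expect_warning(g2 <- read_edge_list(textConnection(c("a b", "b a", "a b"))),
                 "duplicate")
  expect_equal(g2$m, 1)
})

test_that("malformed and empty inputs raise informative errors", {
  expect_error(read_edge_list(textConnection(c("a b", "c"))), "line 2")
  expect_error(read_edge_list(textConnection(character())),
               "no edges or vertices")
  expect_error(read_edge_list(textConnection("# only a comment")),
               "no edges or vertices")
})

test_that("a vertex-list header keeps isolated vertices", {
  g <- read_edge_list(textConnection(c("# vertices: z q", "a b")))
  expect_identical(g$labels, c("a", "b", "q", "z"))
  # {a},{b},{a,b} plus the singletons {q},{z}
  expect_equal(count_cis(g), 5)
})

test_that("numeric labels sort numerically, mixed labels lexicographically", {
  g <- read_edge_list(textConnection(c("2 10", "9 10")))
  expect_identical(g$labels, c("2", "9", "10"))
  g2 <- read_edge_list(textConnection(c("b a", "a 10")))
  expect_identical(g2$labels, c("10", "a", "b"))
})

test_that("edge-list round trip reproduces the graph bit-exactly", {
  g <- er_graph(15, 0.3, 7)
  path <- withr::local_tempfile()
  write_edge_list(g, path)
  g2 <- read_edge_list(path)
  expect_identical(g[c("n", "labels", "adj", "m")],
                   g2[c("n", "labels", "adj", "m")])
  # reading twice is deterministic
  g3 <- read_edge_list(path)
  expect_identical(g2, g3)
})

test_that("binary-matrix attribute dialect parses and aligns to ids", {
  g <- graph_from_pairs("a-b")
  ag <- read_attributes(textConnection(c("a 1 0 1", "b 1 1 0")), g)
  expect_equal(ag$d, 3)
  expect_identical(unname(ag$features["a", ]), c(1L, 0L, 1L))
  expect_identical(unname(ag$features["b", ]), c(1L, 1L, 0L))
  expect_identical(ag$feature_names, c("1", "2", "3"))
})

test_that("feature-list attribute dialect builds sorted dimensions", {
  g <- graph_from_pairs("a-b")
  ag <- read_attributes(textConnection(c("a fx,fz", "b fx,fy")), g)
  expect_equal(ag$d, 3)
  expect_identical(ag$feature_names, c("fx", "fy", "fz"))
  expect_identical(unname(ag$features["a", ]), c(1L, 0L, 1L))
  expect_identical(unname(ag$features["b", ]), c(1L, 1L, 0L))
})

test_that("attribute table errors name the offending vertex or value", {
  g <- graph_from_pairs("a-b")
  expect_error(read_attributes(textConnection("a 1 0"), g), "'b' missing")
  expect_error(read_attributes(textConnection(c("a 1 0", "b 1 2")), g),
               "non-binary")
  expect_error(read_attributes(textConnection(c("a 1 0", "b 1")), g),
               "expected 2 attribute columns")
  expect_error(read_attributes(textConnection(c("a 1", "a 1", "b 1")), g),
               "more than once")
})

test_that("vertex sets are written as sorted tab-separated labels", {
  g <- graph_from_pairs(c("a-b", "b-c"))
  con <- textConnection("out", "w", local = TRUE)
  n <- write_vertex_sets(list(c(1, 3), 2), g, con)
  close(con)
  expect_equal(n, 2)
  expect_identical(out, c("a\tc", "b"))

  con2 <- textConnection("out2", "w", local = TRUE)
  expect_equal(write_vertex_sets(list(), g, con2), 0)
  close(con2)
  expect_identical(out2, character())

  con3 <- textConnection("out3", "w", local = TRUE)
  write_vertex_sets(list(c(3, 1, 2)), g, con3)
  close(con3)
  expect_identical(out3, "a\tb\tc")

  expect_error(write_vertex_sets(list(5), g, textConnection("x", "w")),
               "out of range")
})
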