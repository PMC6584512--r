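# The bundled attributed example (vertices A,B,C,F,G,H over d = 6) drives
# most of the single-operation checks; its signatures are small enough to
# verify by hand.

test_that("feature signatures AND member features; empty set is all ones", {
  ag <- example_attributed_graph()
  expect_identical(unname(feature_signature(ag, integer())), rep(TRUE, 6))
  A <- 1L
  expect_identical(unname(feature_signature(ag, A)),
                   c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  # A({A,B}) = f(A) & f(B) = f1,f2,f3,f4
  expect_identical(unname(which(feature_signature(ag, c(1, 2)))), 1:4)
  # incremental form: sig(U + v) = sig(U) & f(v)
  sAB <- feature_signature(ag, c(1, 2))
  expect_identical(feature_signature(ag, c(1, 2, 6)),
                   sAB & (ag$features[6, ] == 1L))
})

test_that("cohesion thresholds behave and degenerate s_min = 0 passes all", {
  sig <- c(TRUE, FALSE, FALSE, TRUE)
  expect_true(is_cohesive(sig, 2))
  expect_false(is_cohesive(sig, 3))
  expect_true(is_cohesive(c(FALSE, FALSE), 0))
  expect_true(is_cohesive(sig, mining_config(1)))
})

test_that("candidates sort by (distance, id) with id tie-break", {
  ag <- example_attributed_graph()
  st <- enum_state_for(ag$graph, c(1, 2)) # {A,B}
  # F and H at distance 1; C and G at distance 2 through B
  expect_identical(order_candidates(st, state_candidates(st)),
                   c(4L, 6L, 3L, 5L))
})

test_that("covering-sibling prune drops exactly the covered branches", {
  ag <- example_attributed_graph()
  # at {A}: keep B; F and H are covered by B
  stA <- enum_state_new(ag$graph, 1)
  ordA <- order_candidates(stA, state_candidates(stA))
  expect_identical(ordA, c(2L, 4L, 6L))
  expect_identical(
    prune_covered_siblings(ag, feature_signature(ag, 1), ordA),
    c(TRUE, FALSE, FALSE))
  # at {A,B}: keep F and H; C and G are covered by H
  stAB <- enum_state_for(ag$graph, c(1, 2))
  ordAB <- order_candidates(stAB, state_candidates(stAB))
  expect_identical(
    prune_covered_siblings(ag, feature_signature(ag, c(1, 2)), ordAB),
    c(TRUE, TRUE, FALSE, FALSE))
  # incomparable signatures are both kept
  g2 <- graph_from_pairs(c("a-b", "a-c"))
  ag2 <- cis_attributed_graph(g2, rbind(c(1, 1), c(1, 0), c(0, 1)))
  st2 <- enum_state_new(ag2$graph, 1)
  expect_identical(
    prune_covered_siblings(ag2, feature_signature(ag2, 1), c(2L, 3L)),
    c(TRUE, TRUE))
})

test_that("level-one pruning follows the dominated-root rule", {
  ag <- example_attributed_graph()
  expect_false(level_one_keep(ag, 3)) # C: f(C) within f(B), B < C
  expect_false(level_one_keep(ag, 6)) # H: f(H) within f(A), A < H
  expect_true(level_one_keep(ag, 1))
  expect_true(level_one_keep(ag, 2))
  expect_true(level_one_keep(ag, 4))
  expect_true(level_one_keep(ag, 5))
  # a vertex with no neighbors is always kept
  gi <- cis_graph(cbind("a", "b"), vertices = "z")
  agi <- cis_attributed_graph(gi, matrix(1L, 3, 2))
  expect_true(level_one_keep(agi, 3))
})

test_that("parent-identical cutoff detects signature equality", {
  ag <- example_attributed_graph()
  sABF <- feature_signature(ag, c(1, 2, 4))
  sABFH <- feature_signature(ag, c(1, 2, 4, 6))
  expect_true(same_as_parent_cutoff(sABF, sABFH))
  expect_false(same_as_parent_cutoff(c(TRUE, TRUE, FALSE),
                                     c(TRUE, FALSE, FALSE)))
})

test_that("maximality scans all graph neighbors", {
  ag <- example_attributed_graph()
  expect_true(is_maximal(ag, c(1, 2, 4, 5, 6), 2))  # {A,B,F,G,H}
  expect_false(is_maximal(ag, c(1, 2), 2))          # extendable by H
  gi <- cis_graph(cbind("a", "b"), vertices = "z")
  agi <- cis_attributed_graph(gi, rbind(c(1, 1), c(0, 0), c(1, 1)))
  expect_true(is_maximal(agi, 3, 2))                # isolated cohesive vertex
})

test_that("the miner agrees with the oracle and reports an antichain", {
  for (seed in 1:6) {
    pg <- planted_attributed_graph(planted_model(
      n = 9, density = 0.3, d = 4, modules = list(c(4, 3)),
      background_rate = 0.3, seed = seed))
    smin <- 1 + (seed %% 3)
    want <- brute_force_maximal_cohesive(pg$agraph, smin)$sets
    got <- mine_maximal_cohesive(pg$agraph, smin)
    expect_same_sets(got$sets, want)
    # antichain: no reported set contains another
    keys <- lapply(got$sets, as.integer)
    for (i in seq_along(keys)) for (j in seq_along(keys)) {
      if (i != j) expect_false(all(keys[[i]] %in% keys[[j]]))
    }
    # every reported set is connected, cohesive, and unextendable
    for (k in seq_along(got$sets)) {
      S <- got$sets[[k]]
      expect_false(anyNA(cismine:::bfs_distances(pg$agraph$graph, S, min(S))))
      expect_true(is_cohesive(feature_signature(pg$agraph, S), smin))
      expect_true(is_maximal(pg$agraph, S, smin))
    }
  }
})

test_that("degenerate mining cases", {
  g <- graph_from_pairs(c("a-b", "c-d"))
  # all-zero attributes: nothing is cohesive
  ag0 <- cis_attributed_graph(g, matrix(0L, 4, 3))
  expect_length(mine_maximal_cohesive(ag0, 1)$sets, 0)
  # s_min = 0: exactly the connected components
  ag1 <- cis_attributed_graph(g, matrix(rbinom(12, 1, 0.5), 4, 3))
  expect_same_sets(mine_maximal_cohesive(ag1, 0)$sets, list(1:2, 3:4))
  # s_min above d is a data error
  expect_error(mine_maximal_cohesive(ag1, 99), "S_min exceeds")
})

test_that("raising s_min only shrinks or splits reported sets", {
  pg <- planted_attributed_graph(planted_model(
    n = 10, density = 0.35, d = 5, modules = list(c(5, 4)),
    background_rate = 0.4, seed = 9))
  for (t in 3:1) {
    hi <- mine_maximal_cohesive(pg$agraph, t)$sets
    lo <- mine_maximal_cohesive(pg$agraph, t - 1)$sets
    for (S in hi) {
      expect_true(any(vapply(lo, function(L) all(S %in% L), logical(1))))
    }
  }
})
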