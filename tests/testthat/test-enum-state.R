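# The 14-vertex example graph realizes the documented distance-array
# state for U = {2,3,4,5,7,9}; these tests walk that state.

test_that("anchor and utmost of the 14-vertex worked example", {
  g <- example_graph_14()
  U <- c(2, 3, 4, 5, 7, 9)
  expect_equal(anchor_vertex(U), 2)
  expect_equal(utmost_vertex(g, U), 9)
  st <- enum_state_for(g, U)
  expect_equal(st$D[9], 3)
  # members are appended in strictly increasing (distance, id) order
  expect_identical(state_members(st), c(2L, 3L, 5L, 4L, 7L, 9L))
})

test_that("extending the worked example with vertex 10 and backtracking", {
  g <- example_graph_14()
  st <- enum_state_for(g, c(2, 3, 4, 5, 7, 9))
  before <- state_snapshot(st)
  expect_true(is_valid_child(st, 10))
  state_extend(st, 10)
  expect_equal(st$D[11], 4)
  expect_equal(st$D[12], 4)
  expect_equal(st$P[11], 10)
  expect_equal(st$P[12], 10)
  expect_identical(state_members(st), c(2L, 3L, 5L, 4L, 7L, 9L, 10L))
  state_backtrack(st)
  expect_identical(state_snapshot(st), before)
})

test_that("anchor requires a non-empty set; utmost requires connectivity", {
  expect_error(anchor_vertex(integer()), "empty")
  g <- graph_from_pairs(c("a-b", "c-d"))
  expect_error(utmost_vertex(g, c(1, 3)), "connected")
  expect_equal(anchor_vertex(5), 5)
})

test_that("utmost ties go to the larger id", {
  # a-b, a-c: b and c both at distance 1 from anchor a
  g <- graph_from_pairs(c("a-b", "a-c"))
  expect_equal(utmost_vertex(g, 1:3), 3)
  # 4-cycle: opposite corner is unique at distance 2
  g2 <- family_graph("cycle", 4)
  expect_equal(utmost_vertex(g2, 1:4), 3)
})

test_that("parent_of deletes the utmost vertex and reaches the empty set", {
  g <- example_graph_14()
  expect_identical(parent_of(g, c(2, 3, 4, 5, 7, 9, 10)),
                   c(2L, 3L, 4L, 5L, 7L, 9L))
  expect_identical(parent_of(g, 5), integer())
  p3 <- graph_from_pairs(c("a-b", "b-c"))
  expect_identical(parent_of(p3, 1:3), c(1L, 2L))
  # repeated application terminates at the empty set
  S <- c(2, 3, 4, 5, 7, 9)
  for (i in seq_along(S)) S <- parent_of(g, S)
  expect_identical(S, integer())
})

test_that("child validity matches the sample-graph discussion", {
  g <- sample_graph_4() # A-B, A-D, B-C, B-D, C-D
  A <- 1L; B <- 2L; C <- 3L; D <- 4L
  # D cannot extend {A,B,C}: distance(A,D)=1 < distance(A,C)=2
  st <- enum_state_for(g, c(A, B, C))
  expect_false(is_valid_child(st, D))
  # C cannot extend {B,D}: equal distances but C < D
  st2 <- enum_state_for(g, c(B, D))
  expect_false(is_valid_child(st2, C))
  # A cannot extend {B}: below the anchor
  st3 <- enum_state_new(g, B)
  expect_false(is_valid_child(st3, A))
  # vertex 10 is a valid extension of the worked-example state
  st4 <- enum_state_for(example_graph_14(), c(2, 3, 4, 5, 7, 9))
  expect_true(is_valid_child(st4, 10))
  expect_error(is_valid_child(st4, 9), "already a member")
})

test_that("extend rejects non-candidates and invalid children", {
  g <- sample_graph_4()
  st <- enum_state_for(g, c(1, 2, 3)) # {A,B,C}
  expect_error(state_extend(st, 4), "not a valid child|not a live candidate")
  st2 <- enum_state_new(g, 1)
  expect_error(state_backtrack(st2), "root")
})

test_that("extend/backtrack is an exact involution on random states", {
  for (seed in 1:5) {
    g <- er_graph(10, 0.35, seed)
    for (root in c(1, 2, 3)) {
      st <- enum_state_new(g, root)
      # random downward walk, snapshotting at each depth
      snaps <- list(state_snapshot(st))
      depth <- 0
      withr::with_seed(seed * 100 + root, {
        repeat {
          live <- state_candidates(st)
          if (length(live) == 0 || depth >= 4) break
          state_extend(st, live[sample.int(length(live), 1)])
          depth <- depth + 1
          snaps[[depth + 1]] <- state_snapshot(st)
        }
      })
      while (depth > 0) {
        state_backtrack(st)
        depth <- depth - 1
        expect_identical(state_snapshot(st), snaps[[depth + 1]])
      }
    }
  }
})

test_that("singleton root on an isolated vertex has no candidates", {
  g <- cis_graph(cbind("a", "b"), vertices = "z")
  st <- enum_state_new(g, 3)
  expect_identical(state_candidates(st), integer())
  expect_identical(state_members(st), 3L)
})
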