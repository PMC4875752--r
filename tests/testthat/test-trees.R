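test_that("parse_newick builds validated bifurcating trees", {
  tr <- parse_newick("((a,b),c);")
  expect_equal(n_tips(tr), 3L)
  expect_equal(n_nodes(tr), 5L)
  tr2 <- parse_newick("((a,b)x,c)r;")
  expect_equal(sort(tr2$node_label), c("r", "x"))
  expect_error(parse_newick("(a);"), "at least 2 tips")
  expect_error(parse_newick("((a,b,c),d);"), "[Pp]olytomy")
  expect_error(parse_newick("((a,b),a);"), "unique")
  expect_error(parse_newick("((a,b),c;"), "position")
})

test_that("newick round trip preserves the labelled topology", {
  set.seed(101)
  for (k in 1:100) {
    n <- sample(2:40, 1)
    tr <- if (k %% 2) sim_yule_tree(n) else sim_uniform_tree(n)
    back <- parse_newick(write_newick(tr))
    expect_true(trees_isomorphic(tr, back))
  }
})

test_that("levels follow the max-distance-to-leaves definition", {
  cat8 <- parse_newick(caterpillar_newick(8))
  expect_equal(node_level(cat8, "a1"), 0L)
  expect_equal(tree_height(cat8), 7L)       # n - 1 for the caterpillar
  bal8 <- parse_newick(balanced_newick(3))
  expect_equal(tree_height(bal8), 3L)       # lg 8 for the balanced tree
  expect_true(all(node_level(bal8)[seq_len(8)] == 0L))
  expect_error(node_level(bal8, "nope"), "unknown node")
})

test_that("level profiles count nodes per level and sum to 2n-1", {
  p4 <- level_profile(parse_newick(caterpillar_newick(4)))
  expect_equal(p4$count, c(4L, 1L, 1L, 1L))
  b4 <- level_profile(parse_newick(balanced_newick(2)))
  expect_equal(b4$count, c(4L, 2L, 1L))
  set.seed(7)
  for (k in 1:100) {
    n <- sample(2:50, 1)
    tr <- if (k %% 2) sim_yule_tree(n) else sim_uniform_tree(n)
    prof <- level_profile(tr)
    expect_equal(sum(prof$count), 2L * n - 1L)
    expect_equal(prof$count[1], n)
  }
})

test_that("ancestry queries match path enumeration and brute force", {
  tr <- parse_newick("((a,b)x,c)r;")
  expect_equal(lca_node(tr, "a", "a"), resolve_node(tr, "a"))
  expect_equal(lca_node(tr, "a", "c"), resolve_node(tr, "r"))
  expect_equal(edge_distance(tr, "r", "a"), 2L)
  expect_equal(edge_distance(tr, "r", "c"), 1L)
  expect_error(edge_distance(tr, "a", "c"), "incomparable")
  expect_false(is_ancestor(tr, "a", "a"))           # strict by default
  expect_true(is_ancestor(tr, "a", "a", strict = FALSE))

  set.seed(11)
  for (k in 1:50) {
    tr <- sim_uniform_tree(10)
    # transitive-closure reference
    anc <- matrix(FALSE, tr$n_nodes, tr$n_nodes)
    for (v in seq_len(tr$n_nodes)) {
      u <- v
      while (u != tr$root) {
        u <- tr$parent[u]
        anc[u, v] <- TRUE
      }
    }
    pairs <- cbind(sample(tr$n_nodes, 25, TRUE), sample(tr$n_nodes, 25, TRUE))
    for (i in seq_len(nrow(pairs))) {
      expect_identical(is_ancestor(tr, pairs[i, 1], pairs[i, 2]),
                       anc[pairs[i, 1], pairs[i, 2]])
    }
  }
})

test_that("cophy_tree rejects malformed structures", {
  expect_error(cophy_tree(c(0L, 1L), matrix(0L, 2, 2), c("a", "b")),
               "exactly")
})
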