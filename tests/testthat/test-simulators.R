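test_that("generators produce valid dated bifurcating trees", {
  expect_error(sim_yule_tree(1), "at least 2")
  expect_error(sim_uniform_tree(1), "at least 2")
  set.seed(61)
  cherry <- sim_yule_tree(2)
  expect_equal(n_nodes(cherry), 3L)
  expect_equal(node_rank(cherry)[cherry$root], 1L)
  expect_equal(n_nodes(sim_uniform_tree(2)), 3L)
  for (k in 1:40) {
    n <- sample(2:60, 1)
    tr <- if (k %% 2) sim_yule_tree(n) else sim_uniform_tree(n)
    expect_equal(n_nodes(tr), 2L * n - 1L)
    expect_true(validate_dating(tr))
  }
})

test_that("a fixed seed reproduces tanglegrams bit for bit", {
  a <- write_tanglegram(sim_tanglegram(50, "yule", seed = 7))
  b <- write_tanglegram(sim_tanglegram(50, "yule", seed = 7))
  expect_identical(a, b)
  c2 <- write_tanglegram(sim_tanglegram(50, "yule", seed = 8))
  expect_false(identical(a, c2))
  reps <- sim_tanglegrams(12, reps = 3, model = "uniform", seed = 5)
  reps2 <- sim_tanglegrams(12, reps = 3, model = "uniform", seed = 5)
  expect_identical(lapply(reps, write_tanglegram),
                   lapply(reps2, write_tanglegram))
  expect_false(identical(write_tanglegram(reps[[1]]),
                         write_tanglegram(reps[[2]])))
})

test_that("tanglegrams have equal-sized trees and a bijective default map", {
  tg <- sim_tanglegram(10, "yule", seed = 2)
  expect_equal(n_nodes(tg$host), 19L)
  expect_equal(n_nodes(tg$parasite), 19L)
  expect_equal(nrow(tg$associations), 10L)
  expect_equal(anyDuplicated(tg$associations$host), 0L)
  tf <- sim_tanglegram(30, "yule", seed = 2, fan_out = TRUE)
  expect_gt(anyDuplicated(tf$associations$host), 0L)
})

test_that("tree heights stay within the binary-tree bounds", {
  set.seed(71)
  for (model in c("yule", "uniform")) {
    h <- replicate(30, tree_height(sim_tanglegram(100, model)$parasite))
    expect_true(all(h >= ceiling(log2(100))))
    expect_true(all(h <= 99))
  }
})

test_that("level-1 (cherry) counts match the exact expectations", {
  # E[cherries] is exactly n/3 under Yule; under PDA it is
  # n(n-1)/(2(2n-3)), which the n/4 model approximates from above.
  # Deeper levels of the g(i) model are asymptotic approximations, not
  # exact expectations (every 4-leaf tree has one level-2 node, the model
  # predicts 8/9), so only the exact level-1 laws are asserted here.
  set.seed(81)
  reps <- 200
  lvl_counts <- function(tr, i) sum(node_level(tr) == i)
  for (n in c(300, 900)) {
    x <- replicate(reps, lvl_counts(sim_yule_tree(n), 1))
    se <- stats::sd(x) / sqrt(reps)
    expect_lt(abs(mean(x) - n / 3), 3 * se)
  }
  x <- replicate(reps, lvl_counts(sim_uniform_tree(400), 1))
  se <- stats::sd(x) / sqrt(reps)
  exact <- 400 * 399 / (2 * (2 * 400 - 3))
  expect_lt(abs(mean(x) - exact), 3 * se)
  expect_lt(abs(exact - g_level("uniform", 1, 400)), 0.5)
})

test_that("the Uniform model samples labeled topologies uniformly at n=3", {
  set.seed(91)
  draws <- 3000
  outgroup <- replicate(draws, {
    tr <- sim_uniform_tree(3)
    kids <- tr$children[, tr$root]
    tr$tip_label[kids[kids <= 3]]
  })
  p <- table(factor(outgroup, levels = c("t1", "t2", "t3"))) / draws
  se <- sqrt((1 / 3) * (2 / 3) / draws)
  expect_true(all(abs(p - 1 / 3) < 3 * se))
})
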