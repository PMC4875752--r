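test_that("the site recurrence and its closed form agree", {
  expect_equal(a_sites(0), 1)
  expect_equal(a_sites(1), 3)
  expect_equal(a_sites(3), 18)                       # 8 + 8 + 2 = 5*4 - 2
  expect_equal(a_sites(0:50), a_sites(0:50, form = "recurrence"))
  expect_identical(a_sites_exact(0:60, "closed"),
                   a_sites_exact(0:60, "recurrence"))
  expect_error(a_sites(-1), "non-negative")
})

test_that("the current site budget undercuts the previous one", {
  expect_equal(f_sites(0, 5), 1)
  expect_equal(f_sites(2, 1000), 8)
  expect_equal(f_sites(2, 1000, version = "previous"), 27)
  for (i in 0:30) {
    expect_lte(f_sites(i, 1e6), f_sites(i, 1e6, version = "previous"))
  }
  expect_equal(f_sites(40, 1e6), 1e6)                # both saturate at n
  expect_equal(f_sites(40, 1e6, version = "previous"), 1e6)
})

test_that("the level threshold satisfies its defining inequality", {
  expect_equal(level_threshold(30), 4L)
  expect_true(5 * 2^(2) - 2 < 30)                    # i = 3 < threshold
  expect_equal(level_threshold(2), 1L)
  for (n in c(5, 17, 64, 1000, 4094, 4095)) {
    thr <- level_threshold(n)
    i <- seq_len(max(thr - 1, 0))
    expect_true(all(5 * 2^(i - 1) - 2 < n))
  }
})

test_that("expected level counts and their totals behave", {
  expect_equal(g_level("yule", 1, 300), 100)
  expect_equal(g_level("yule", 2, 900), 200)
  expect_equal(g_level("uniform", 1, 400), 100)
  expect_error(g_level("yule", 0, 100), "i >= 1")
  # the level series is geometric (ratio < 1) and totals the ~n internal
  # nodes in the limit; partial sums stay strictly below n
  for (model in c("yule", "uniform")) {
    s <- sum(g_level(model, 1:20, 1000))
    expect_lt(s, 1000)
    expect_gt(s, 980)
  }
})

test_that("space bounds track their stated asymptotic exponents", {
  expect_equal(space_exponent("yule"), 1.42)
  expect_equal(space_exponent("uniform"), 1.58)
  expect_equal(space_exponent("yule", rounded = FALSE), 3 - log2(3))
  ns <- round(10^seq(2, 6, length.out = 9))
  ry <- sapply(ns, function(n) space_bound("yule", n) / n^1.42)
  ru <- sapply(ns, function(n) space_bound("uniform", n) / n^1.58)
  expect_true(all(ry < 5.1))       # bounded above by a constant
  expect_true(all(ru < 3.3))
  expect_true(all(ry > 0) && all(ru > 0))
})

test_that("tree-space integrals give the printed region of interest", {
  ts <- tree_space_fraction(10, 2500)
  expect_equal(round(ts$s_star), 154632)
  expect_equal(round(ts$s_t), 3097866)
  expect_equal(round(100 * ts$fraction, 2), 4.99)
  # the realistic fraction keeps shrinking towards the limit 0
  f <- sapply(c(100, 1000, 10000, 1e5, 1e6), function(hi)
    tree_space_fraction(10, hi)$fraction)
  expect_true(all(diff(f) < 0))
  expect_error(tree_space_fraction(50, 50), "lo < hi")
})

test_that("memory arithmetic reproduces the worked storage comparison", {
  expect_equal(memory_model(200, 300, layout = "matrix")$sites, 239001)
  expect_equal(memory_model(200, 300, layout = "sublinear")$sites, 19319)
  m1 <- memory_model(200, 300, layout = "matrix")
  s1 <- memory_model(200, 300, layout = "sublinear")
  expect_equal(m1$bytes / m1$sites, 36)              # 36 bytes per site
  expect_equal(format_bytes(m1$bytes, digits = 1), "8.2 MB")
  expect_equal(format_bytes(s1$bytes), "679 KB")
  expect_equal(round(m1$sites / s1$sites), 12)       # the twelve-fold saving
  expect_equal(format_bytes(memory_model(200, 300, 1000,
                                         "sublinear")$bytes), "663 MB")
  expect_equal(format_bytes(memory_model(4000, 4000, 10000,
                                         "sublinear")$bytes), "492 GB")
  tb <- memory_model(4000, 4000, 10000, "matrix")$bytes / 1024^4
  expect_equal(floor(tb), 20)          # the quadratic table needs ~20 TB
})

test_that("expected per-node site counts collapse to the time exponents", {
  expect_equal(expected_complexities("yule", 100)$m_expected, 100^0.42)
  expect_equal(expected_complexities("uniform", 64)$m_expected, 64^0.58)
  expect_equal(expected_complexities("uniform", 10)$time_exponent, 2.17)
  expect_equal(round(1 + 2 * 0.42, 2), 1.84)
})

test_that("observed space never exceeds the realized per-level budget", {
  set.seed(133)
  for (k in 1:20) {
    tg <- sim_tanglegram(sample(5:40, 1), if (k %% 2) "yule" else "uniform")
    rec <- solve_dtr(tg)
    prof <- rec$space_profile
    cap <- pmin(a_sites(pmax(prof$level, 1)) * (prof$level > 0) +
                  (prof$level == 0), 2 * n_tips(tg$host) - 1)
    expect_true(all(prof$sites <= cap * prof$nodes))
  }
})
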