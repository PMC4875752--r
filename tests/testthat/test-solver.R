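HOST3 <- apply_dating(parse_newick("((a,b)x,c)r;"), c(r = 1, x = 2))

test_that("classify_event labels the four-event semantics", {
  ev <- classify_event(HOST3, "r", "a", "c")
  expect_equal(ev$event, "codivergence")
  expect_equal(ev$losses, 1L)          # x intervenes on the r -> a path
  ev <- classify_event(HOST3, "a", "a", "a")
  expect_equal(ev$event, "duplication")
  expect_equal(ev$losses, 0L)
  cherry <- apply_dating(parse_newick("(a,b)r;"))
  ev <- classify_event(cherry, "a", "a", "b")
  expect_equal(ev$event, "host_switch")  # pendant edges coexist
  expect_equal(ev$losses, 0L)
  # children placed above the parent: no event covers it
  expect_false(classify_event(HOST3, "a", "r", "a")$feasible)
  # a switch onto an internal lineage that closed before the take-off edge
  # opened is infeasible
  d <- apply_dating(parse_newick("(((a,b)x,c)y,(d,e)w)r;"),
                    c(r = 1, w = 2, y = 3, x = 4))
  expect_false(classify_event(d, "x", "x", "w")$feasible)
})

test_that("leaf mapping sites are exactly the associations at cost 0", {
  tg <- sim_tanglegram(8, "uniform", seed = 13)
  rec <- solve_dtr(tg)
  leaves <- rec$site_table[rec$site_table$level == 0, ]
  expect_equal(nrow(leaves), 8L)                  # one site per leaf, f(0)=1
  expect_true(all(leaves$cost == 0))
  expect_true(all(leaves$event == "leaf"))
  expect_equal(leaves$host_node[order(leaves$parasite_node)],
               tg$phi[seq_len(8)])
})

test_that("cherry parasites resolve to the textbook placements", {
  # matched cherry on a host cherry: one codivergence site at the host root
  ch <- apply_dating(parse_newick("(a,b)r;"))
  tg <- tanglegram(ch, parse_newick("(A,B)z;"), c(A = "a", B = "b"))
  rec <- solve_dtr(tg)
  expect_equal(rec$total_cost, 0)                 # codivergence is free
  expect_equal(unname(rec$counts["codivergence"]), 1L)
  expect_lte(max(rec$sites_per_node), 3L)         # a_1 = 3
  # both parasite leaves on one host leaf: a duplication at cost D = 1
  tg2 <- tanglegram(HOST3, parse_newick("(A,B)z;"), c(A = "a", B = "a"))
  rec2 <- solve_dtr(tg2)
  expect_equal(rec2$total_cost, 1)
  expect_equal(unname(rec2$counts["duplication"]), 1L)
  # codivergence with one loss beats a host switch under (0,1,2,1)
  tg3 <- tanglegram(HOST3, parse_newick("(A,C)z;"), c(A = "a", C = "c"))
  rec3 <- solve_dtr(tg3)
  expect_equal(rec3$total_cost, 1)
  expect_equal(unname(rec3$counts), c(1L, 0L, 0L, 1L))
})

test_that("a congruent tanglegram reconciles by pure codivergence", {
  set.seed(23)
  for (model in c("yule", "uniform")) {
    host <- if (model == "yule") sim_yule_tree(12, "H")
            else sim_uniform_tree(12, "H")
    tg <- tanglegram(host, host, setNames(host$tip_label, host$tip_label))
    rec <- solve_dtr(tg, event_costs(0, 1, 2, 1))
    expect_equal(rec$total_cost, 0)
    expect_equal(unname(rec$counts["codivergence"]), 11L)
    expect_equal(sum(rec$counts[c("duplication", "host_switch", "loss")]), 0L)
  }
})

test_that("the event census reprices to the optimum (cost identity)", {
  set.seed(33)
  for (k in 1:40) {
    tg <- random_small_tanglegram(sample(3:8, 1), sample(2:8, 1))
    cs <- event_costs(sample(0:3, 1), sample(1:4, 1), sample(1:5, 1),
                      sample(0:2, 1))
    rec <- solve_dtr(tg, cs)
    expect_equal(total_cost(rec$counts, cs), rec$total_cost,
                 tolerance = 1e-12)
    expect_equal(sum(rec$counts[1:3]), tg$parasite$n_tips - 1L)
  }
})

test_that("reported host switches are time-consistent placements", {
  set.seed(43)
  found <- 0L
  for (k in 1:60) {
    tg <- random_small_tanglegram(6, 6, "uniform")
    rec <- solve_dtr(tg)
    pl <- rec$placement
    for (v in which(pl$event == "host_switch")) {
      kids <- tg$parasite$children[, pl$parasite_node[v]]
      ev <- classify_event(tg$host, pl$host_node[v],
                           pl$host_node[match(kids[1], pl$parasite_node)],
                           pl$host_node[match(kids[2], pl$parasite_node)])
      expect_true(ev$feasible)
      expect_equal(ev$event, "host_switch")
      found <- found + 1L
    }
  }
  expect_gt(found, 0L)   # the suite actually exercised switches
})

test_that("raising any single event cost never lowers the optimum", {
  set.seed(53)
  for (k in 1:25) {
    tg <- random_small_tanglegram(sample(3:6, 1), sample(2:5, 1))
    base <- c(0, 1, 2, 1)
    opt0 <- solve_dtr(tg, event_costs(base[1], base[2], base[3],
                                      base[4]))$total_cost
    for (j in 1:4) {
      up <- base; up[j] <- up[j] + sample(1:3, 1)
      expect_gte(solve_dtr(tg, event_costs(up[1], up[2], up[3],
                                           up[4]))$total_cost, opt0)
    }
  }
})

test_that("total_cost is the exact linear combination", {
  expect_equal(total_cost(c(2, 1, 1, 1), event_costs(0, 1, 2, 1)), 4)
  expect_equal(total_cost(c(0, 0, 0, 0), event_costs(3, 4, 5, 6)), 0)
  expect_equal(total_cost(c(7, 0, 0, 0), event_costs(0, 1, 2, 1)), 0)
  expect_error(total_cost(c(-1, 0, 0, 0)), "non-negative")
  expect_error(event_costs(-1, 1, 1, 1), "non-negative")
})

test_that("tidy and glance expose the reconciliation as tibbles", {
  tg <- sim_tanglegram(9, "yule", seed = 77)
  rec <- solve_dtr(tg)
  td <- tidy(rec)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), n_nodes(tg$parasite))
  gl <- glance(rec)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$retained_sites, rec$retained_sites)
  expect_lt(gl$occupancy, 1)
  expect_s3_class(autoplot(rec), "ggplot")
})
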