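# shared fixtures: all built in code, no files

caterpillar_newick <- function(n, prefix = "a") {
  tips <- paste0(prefix, seq_len(n))
  out <- sprintf("(%s,%s)", tips[1], tips[2])
  for (k in seq_len(n - 2) + 2) out <- sprintf("(%s,%s)", out, tips[k])
  paste0(out, ";")
}

balanced_newick <- function(k, prefix = "b") {  # 2^k tips
  tips <- as.list(paste0(prefix, seq_len(2^k)))
  while (length(tips) > 1) {
    tips <- lapply(seq_len(length(tips) / 2), function(i) {
      sprintf("(%s,%s)", tips[[2 * i - 1]], tips[[2 * i]])
    })
  }
  paste0(tips[[1]], ";")
}

# host <= nh leaves, parasite <= np leaves, random association map (with
# repetition allowed so many-to-one maps are exercised)
random_small_tanglegram <- function(nh, np, model = c("yule", "uniform")) {
  model <- match.arg(model)
  gen <- if (model == "yule") sim_yule_tree else sim_uniform_tree
  host <- gen(nh, tip_prefix = "H")
  par <- gen(np, tip_prefix = "P")
  tanglegram(host, par,
             data.frame(parasite = par$tip_label,
                        host = sample(host$tip_label, np, replace = TRUE)))
}

# descendant-tip sets of every internal node: a labelled-topology fingerprint
clade_sets <- function(tree) {
  lev <- seq_len(tree$n_nodes)
  tipsets <- vector("list", tree$n_nodes)
  for (v in seq_len(tree$n_tips)) tipsets[[v]] <- tree$tip_label[v]
  for (v in rev(preorder_nodes_t(tree))) {
    k <- tree$children[, v]
    if (k[1] > 0) tipsets[[v]] <- sort(c(tipsets[[k[1]]], tipsets[[k[2]]]))
  }
  sort(vapply(tipsets[(tree$n_tips + 1):tree$n_nodes],
              paste, "", collapse = "|"))
}

preorder_nodes_t <- function(tree) {
  out <- integer(tree$n_nodes)
  stack <- tree$root; k <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    k <- k + 1L; out[k] <- v
    if (tree$children[1, v] > 0) {
      stack <- c(stack, tree$children[2, v], tree$children[1, v])
    }
  }
  out
}

trees_isomorphic <- function(t1, t2) {
  identical(sort(t1$tip_label), sort(t2$tip_label)) &&
    identical(clade_sets(t1), clade_sets(t2))
}

# structural equality of tanglegrams: topologies, labels, ranks (matched by
# internal-node clade), and associations
tanglegrams_equal <- function(a, b) {
  rank_by_clade <- function(tree) {
    cl <- character(tree$n_nodes)
    for (v in seq_len(tree$n_tips)) cl[v] <- tree$tip_label[v]
    for (v in rev(preorder_nodes_t(tree))) {
      k <- tree$children[, v]
      if (k[1] > 0) {
        cl[v] <- paste(sort(strsplit(paste(cl[k[1]], cl[k[2]], sep = "|"),
                                     "\\|")[[1]]), collapse = "|")
      }
    }
    ids <- (tree$n_tips + 1):tree$n_nodes
    setNames(tree$rank[ids], cl[ids])
  }
  trees_isomorphic(a$host, b$host) &&
    trees_isomorphic(a$parasite, b$parasite) &&
    identical(rank_by_clade(a$host)[order(names(rank_by_clade(a$host)))],
              rank_by_clade(b$host)[order(names(rank_by_clade(b$host)))]) &&
    identical(as.data.frame(a$associations[order(a$associations$parasite), ]),
              as.data.frame(b$associations[order(b$associations$parasite), ]))
}

expect_three_way_agreement <- function(tg, costs) {
  o1 <- solve_dtr(tg, costs)$total_cost
  o2 <- dtr_full_table(tg, costs)$optimum
  o3 <- dtr_brute_force(tg, costs)
  expect_equal(o1, o2, tolerance = 1e-9)
  expect_equal(o2, o3, tolerance = 1e-9)
  invisible(o1)
}
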