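# renumber a grown tree (temporary ids) into the canonical layout: tips
# 1..n and internals n+1..2n-1 in preorder appearance, internal ranks
# carried across the renumbering. Tip labels follow leaf creation order
# (temporary ids are assigned incrementally), so label k marks the k-th
# leaf the generator produced — this keeps labeled-topology statistics
# (e.g. PDA uniformity) observable from the labels.
canonical_tree <- function(parent, kid1, kid2, rank, root, tip_prefix) {
  N <- length(parent)
  n <- (N + 1L) %/% 2L
  pre <- integer(N)
  stack <- integer(N); stack[1L] <- root; top <- 1L
  k <- 0L
  while (top > 0L) {
    v <- stack[top]; top <- top - 1L
    k <- k + 1L; pre[k] <- v
    if (kid1[v] > 0L) {
      stack[top + 1L] <- kid2[v]; stack[top + 2L] <- kid1[v]
      top <- top + 2L
    }
  }
  is_tip <- kid1[pre] == 0L
  newid <- integer(N)
  newid[pre[is_tip]] <- seq_len(n)
  newid[pre[!is_tip]] <- n + seq_len(n - 1L)
  parent2 <- integer(N); children <- matrix(0L, 2L, N)
  for (v in seq_len(N)) {
    w <- newid[v]
    parent2[w] <- if (parent[v] == 0L) 0L else newid[parent[v]]
    if (kid1[v] > 0L) children[, w] <- c(newid[kid1[v]], newid[kid2[v]])
  }
  tip_label <- character(n)
  tip_old <- sort(which(kid1 == 0L))     # creation order of surviving leaves
  tip_label[newid[tip_old]] <- paste0(tip_prefix, seq_len(n))
  tree <- cophy_tree(parent2, children, tip_label,
                     paste0(tip_prefix, "x", seq_len(n - 1L)))
  rk <- integer(n - 1L)
  internal_old <- which(kid1 > 0L)
  rk[newid[internal_old] - n] <- rank[internal_old]
  apply_dating(tree, rk)
}

#' Simulate a Yule (pure-birth) tree
#'
#' Grows a tree by repeatedly choosing a current leaf uniformly at random to
#' bifurcate, until `n` leaves exist — the equal-rates-Markov model, ignoring
#' branch lengths. Internal nodes are dated by birth order (the root has
#' rank 1), the natural total order of the pure-birth process. Yule trees are
#' the balanced end of the realistic tree-shape spectrum; their expected
#' number of internal nodes at level `i` is `2^(i-1) n / 3^i`.
#'
#' @param n number of leaves (>= 2).
#' @param tip_prefix label prefix; tips become `<prefix>1..<prefix>n`,
#'   internal nodes `<prefix>x1..`.
#' @return A `dated_cophy_tree`. Uses the current RNG state.
#' @export
sim_yule_tree <- function(n, tip_prefix = "t") {
  n <- as.integer(n)
  if (n < 2L) stop("n must be at least 2")
  N <- 2L * n - 1L
  parent <- integer(N); kid1 <- integer(N); kid2 <- integer(N)
  rank <- integer(N)
  kid1[1L] <- 2L; kid2[1L] <- 3L; parent[2L:3L] <- 1L; rank[1L] <- 1L
  leaves <- c(2L, 3L)
  next_id <- 4L; births <- 1L
  while (length(leaves) < n) {
    pick <- sample.int(length(leaves), 1L)
    v <- leaves[pick]
    births <- births + 1L
    rank[v] <- births
    kid1[v] <- next_id; kid2[v] <- next_id + 1L
    parent[next_id + 0:1] <- v
    leaves[pick] <- next_id
    leaves <- c(leaves, next_id + 1L)
    next_id <- next_id + 2L
  }
  canonical_tree(parent, kid1, kid2, rank, 1L, tip_prefix)
}

#' Simulate a Uniform (PDA) tree
#'
#' Samples uniformly over labeled tree shapes by sequential attachment: leaf
#' `k+1` is attached to an edge chosen uniformly among the `2k-1` candidates
#' (every edge plus a notional root stem). The dating is a uniformly random
#' linear extension of the ancestry partial order, sampled by repeatedly
#' drawing one of the currently rankable internal nodes. PDA trees bound the
#' unbalanced end of realistic tree shapes; their expected level-`i` internal
#' node count is `3^(i-1) n / 4^i`.
#'
#' @inheritParams sim_yule_tree
#' @return A `dated_cophy_tree`. Uses the current RNG state.
#' @export
sim_uniform_tree <- function(n, tip_prefix = "t") {
  n <- as.integer(n)
  if (n < 2L) stop("n must be at least 2")
  N <- 2L * n - 1L
  parent <- integer(N); kid1 <- integer(N); kid2 <- integer(N)
  root <- 1L
  nodes <- 1L
  childv <- integer(0)  # non-root nodes, i.e. edges by their lower endpoint
  for (k in seq_len(n - 1L)) {
    slots <- 2L * k - 1L
    s <- sample.int(slots, 1L)
    newint <- nodes + 1L; newleaf <- nodes + 2L; nodes <- nodes + 2L
    if (s == slots) {               # root stem: new internal becomes root
      parent[root] <- newint
      kid1[newint] <- root; kid2[newint] <- newleaf
      parent[newleaf] <- newint
      childv <- c(childv, root, newleaf)
      root <- newint
    } else {                        # subdivide edge above childv[s]
      v <- childv[s]
      p <- parent[v]
      if (kid1[p] == v) kid1[p] <- newint else kid2[p] <- newint
      parent[newint] <- p
      kid1[newint] <- v; kid2[newint] <- newleaf
      parent[v] <- newint; parent[newleaf] <- newint
      childv <- c(childv, newint, newleaf)
    }
  }
  # uniformly random linear extension: repeatedly rank a random internal
  # node whose parent is already ranked
  rank <- integer(N)
  avail <- root
  r <- 0L
  while (length(avail)) {
    pick <- if (length(avail) == 1L) 1L else sample.int(length(avail), 1L)
    v <- avail[pick]
    r <- r + 1L
    rank[v] <- r
    avail <- avail[-pick]
    for (w in c(kid1[v], kid2[v])) {
      if (w > 0L && kid1[w] > 0L) avail <- c(avail, w)
    }
  }
  canonical_tree(parent, kid1, kid2, rank, root, tip_prefix)
}

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

# deterministic per-replicate stream derived from (seed, replicate index)
replicate_seed <- function(seed, k) {
  as.integer((as.double(seed) + 104729 * as.double(k)) %% 2147483646) + 1L
}

#' Simulate a random tanglegram
#'
#' Draws independent host and parasite trees of equal size from the same
#' model (emulating random coevolutionary test sets built from paired Yule
#' or Uniform trees) and associates leaves by a uniformly random map: a
#' bijection by default, or sampling hosts with replacement when
#' `fan_out = TRUE` (several parasites per host leaf).
#'
#' @param n leaves per tree (host and parasite are the same size).
#' @param model `"yule"` or `"uniform"`.
#' @param seed optional integer; when given, the draw is reproducible and
#'   the caller's RNG state is untouched.
#' @param fan_out if `TRUE`, hosts are drawn with replacement.
#' @return A [tanglegram()] with host tips `H1..Hn`, parasite tips `P1..Pn`.
#' @export
#' @examples
#' tg <- sim_tanglegram(10, "yule", seed = 1)
sim_tanglegram <- function(n, model = c("yule", "uniform"), seed = NULL,
                           fan_out = FALSE) {
  model <- match.arg(model)
  gen <- if (model == "yule") sim_yule_tree else sim_uniform_tree
  with_local_seed(seed, {
    host <- gen(n, tip_prefix = "H")
    parasite <- gen(n, tip_prefix = "P")
    hosts <- if (fan_out) sample(host$tip_label, n, replace = TRUE)
             else sample(host$tip_label)
    tanglegram(host, parasite,
               tibble::tibble(parasite = parasite$tip_label, host = hosts))
  })
}

#' @rdname sim_tanglegram
#' @param reps number of replicates; replicate `k` uses an RNG stream derived
#'   deterministically from `(seed, k)`.
#' @return `sim_tanglegrams()`: a list of `reps` tanglegrams.
#' @export
sim_tanglegrams <- function(n, reps, model = c("yule", "uniform"),
                            seed = 1L, fan_out = FALSE) {
  model <- match.arg(model)
  lapply(seq_len(reps), function(k) {
    sim_tanglegram(n, model, seed = replicate_seed(seed, k),
                   fan_out = fan_out)
  })
}
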