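#' Date a host tree
#'
#' A dated host tree carries a total temporal order on its internal nodes: a
#' bijective rank `1..n-1` (1 = oldest divergence) in which every parent
#' strictly predates its children. All leaves are extant and share the
#' notional rank `n`. Fixing this order is what turns the NP-hard cophylogeny
#' reconstruction problem into the polynomially solvable dated tree
#' reconciliation problem.
#'
#' If `ranks` is omitted, ranks are recovered from internal node labels of
#' the form `name#rank` when present; otherwise a canonical dating is
#' synthesized by ordering internal nodes by depth from the root, ties broken
#' by left-to-right traversal order (any ancestry-respecting order is a valid
#' dating). A tree that is already dated is returned unchanged, making the
#' operation idempotent.
#'
#' @param tree a [cophy_tree()].
#' @param ranks optional dating: either an integer vector named by internal
#'   node label, or an unnamed integer vector of length `n-1` ordered by
#'   internal node id (`n+1 .. 2n-1`). Must be a bijection onto `1..n-1`
#'   with `rank(parent) < rank(child)`.
#' @return A `dated_cophy_tree` (inherits from `cophy_tree`) with a `rank`
#'   field over all nodes, leaves at rank `n`.
#' @export
#' @examples
#' apply_dating(parse_newick("((a,b)x,c)r;"), c(r = 1, x = 2))
apply_dating <- function(tree, ranks = NULL) {
  n <- tree$n_tips
  internals <- (n + 1L):tree$n_nodes
  if (is.null(ranks) && inherits(tree, "dated_cophy_tree")) {
    return(tree)
  }
  if (is.null(ranks)) {
    lbl <- tree$node_label
    if (!all(is.na(lbl)) && all(grepl("#\\d+$", lbl[!is.na(lbl)])) &&
        !anyNA(lbl)) {
      ranks <- as.integer(sub("^.*#", "", lbl))
      tree$node_label <- sub("#\\d+$", "", lbl)
      tree$node_label[!nzchar(tree$node_label)] <- NA_character_
    } else {
      # canonical: by depth, then left-to-right (preorder already respects
      # ancestry, so a stable sort on depth keeps parents first)
      pre <- preorder_nodes(tree)
      pre_int <- pre[pre > n]
      depth <- node_depths(tree)
      ord <- pre_int[order(depth[pre_int])]  # stable
      ranks <- integer(n - 1L)
      ranks[ord - n] <- seq_len(n - 1L)
    }
  }
  if (!is.null(names(ranks))) {
    ids <- resolve_node(tree, names(ranks))
    if (any(ids <= n)) stop("ranks must name internal nodes")
    full <- rep(NA_integer_, n - 1L)
    full[ids - n] <- as.integer(ranks)
    ranks <- full
  }
  ranks <- as.integer(ranks)
  if (length(ranks) != n - 1L || anyNA(ranks) ||
      !identical(sort(ranks), seq_len(n - 1L))) {
    stop("ranks must be a bijection from the ", n - 1L,
         " internal nodes onto 1..", n - 1L)
  }
  rank <- c(rep(n, n), ranks)
  for (v in internals) {
    p <- tree$parent[v]
    if (p != 0L && rank[p] >= rank[v]) {
      stop("invalid dating: child ", node_name(tree, v), " (rank ",
           rank[v], ") would predate its parent ", node_name(tree, p),
           " (rank ", rank[p], ")")
    }
  }
  tree$rank <- as.integer(rank)
  class(tree) <- c("dated_cophy_tree", "cophy_tree")
  tree
}

#' @rdname apply_dating
#' @param dated a `dated_cophy_tree`.
#' @export
validate_dating <- function(dated) {
  if (!inherits(dated, "dated_cophy_tree")) stop("tree is not dated")
  n <- dated$n_tips
  rk <- dated$rank
  if (!identical(sort(rk[(n + 1L):dated$n_nodes]), seq_len(n - 1L)) ||
      any(rk[seq_len(n)] != n)) {
    stop("rank is not a bijection onto 1..n-1 with leaves at rank n")
  }
  for (v in seq_len(dated$n_nodes)) {
    p <- dated$parent[v]
    if (p != 0L && rk[p] >= rk[v]) {
      stop("rank(parent) < rank(child) violated at ", node_name(dated, v))
    }
  }
  invisible(TRUE)
}

#' Node ranks of a dated tree
#' @param dated a `dated_cophy_tree`.
#' @return Integer vector of ranks indexed by node id (leaves carry `n`).
#' @export
node_rank <- function(dated) {
  if (!inherits(dated, "dated_cophy_tree")) stop("tree is not dated")
  dated$rank
}

#' Temporal coexistence of two host edges
#'
#' Each host edge `(u, v)` (parent, child) spans the open rank interval
#' `(rank(u), rank(v))`; leaves carry rank `n`, so all pendant edges reach
#' the present and every pair of pendant edges coexists. Two edges coexist
#' iff their intervals overlap; an edge always coexists with itself. Host
#' switches are only allowed between coexisting edges, which is what makes
#' reported maps time-consistent.
#'
#' @param dated a `dated_cophy_tree`.
#' @param e1,e2 edges as length-2 vectors `c(parent, child)` of node ids or
#'   labels.
#' @return Logical.
#' @export
edges_coexist <- function(dated, e1, e2) {
  if (!inherits(dated, "dated_cophy_tree")) stop("tree is not dated")
  iv <- function(e) {
    e <- resolve_node(dated, e)
    if (length(e) != 2L || dated$parent[e[2L]] != e[1L]) {
      stop("not an edge of the host tree: (", e[1L], ", ", e[2L], ")")
    }
    c(dated$rank[e[1L]], dated$rank[e[2L]])
  }
  i1 <- iv(e1); i2 <- iv(e2)
  max(i1[1L], i2[1L]) < min(i1[2L], i2[2L])
}
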