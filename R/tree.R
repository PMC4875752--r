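#' Rooted bifurcating tree container
#'
#' `cophy_tree` objects hold a strictly bifurcating rooted tree in flat
#' arrays: tips are node ids `1..n`, internal nodes `n+1 .. 2n-1`, with the
#' root at `n+1` (ape's convention). The constructor validates that every
#' non-root node has exactly one parent and every internal node exactly two
#' children.
#'
#' @param parent integer vector of length `2n-1`; `parent[v]` is the parent
#'   node id of `v`, `0` for the root.
#' @param children integer matrix with 2 rows and `2n-1` columns; columns of
#'   tips are `0`.
#' @param tip_label character vector of `n` unique, non-empty tip names.
#' @param node_label optional character vector of length `n-1` with internal
#'   node names (internal node `n+k` gets `node_label[k]`); `NA` allowed.
#' @return A `cophy_tree`.
#' @export
cophy_tree <- function(parent, children, tip_label, node_label = NULL) {
  n <- length(tip_label)
  N <- 2L * n - 1L
  parent <- as.integer(parent)
  storage.mode(children) <- "integer"
  if (length(parent) != N || ncol(children) != N) {
    stop("a tree with ", n, " tips must have exactly ", N, " nodes")
  }
  tree <- structure(
    list(n_tips = n, n_nodes = N, parent = parent, children = children,
         tip_label = as.character(tip_label),
         node_label = if (is.null(node_label)) rep(NA_character_, n - 1L)
                      else as.character(node_label),
         root = n + 1L),
    class = "cophy_tree")
  validate_cophy_tree(tree)
  tree
}

validate_cophy_tree <- function(tree) {
  n <- tree$n_tips; N <- tree$n_nodes
  if (n < 2L) stop("trees must have at least 2 tips; the root must bifurcate")
  if (sum(tree$parent == 0L) != 1L || tree$parent[tree$root] != 0L) {
    stop("exactly one root expected at node ", tree$root)
  }
  n_kids <- colSums(tree$children > 0L)
  if (any(n_kids[seq_len(n)] != 0L)) {
    stop("tip nodes must not have children")
  }
  bad <- which(n_kids[(n + 1L):N] != 2L) + n
  if (length(bad)) {
    stop("polytomy or unary node: internal node ",
         node_name(tree, bad[1L]), " has ", n_kids[bad[1L]], " children")
  }
  if (!identical(sort(as.integer(tree$children[tree$children > 0L])),
                 sort(setdiff(seq_len(N), tree$root)))) {
    stop("tree is not connected: every non-root node needs exactly one parent")
  }
  if (anyDuplicated(tree$tip_label) || any(!nzchar(tree$tip_label)) ||
      anyNA(tree$tip_label)) {
    dup <- tree$tip_label[duplicated(tree$tip_label)][1L]
    stop("tip labels must be unique and non-empty",
         if (!is.null(dup) && !is.na(dup)) paste0(": '", dup, "'") else "")
  }
  invisible(tree)
}

node_name <- function(tree, v) {
  n <- tree$n_tips
  if (v <= n) return(tree$tip_label[v])
  lbl <- tree$node_label[v - n]
  if (is.na(lbl) || !nzchar(lbl)) paste0("#", v) else lbl
}

#' Parse a rooted bifurcating Newick string
#'
#' Standard rooted Newick via [ape::read.tree()]; internal node labels are
#' preserved (used for dating), branch lengths are parsed but discarded.
#' Polytomies and duplicate leaf labels are rejected.
#'
#' @param text a Newick string (must end in `;`).
#' @param file alternatively, path to a file whose first tree is read.
#' @return A [cophy_tree()].
#' @export
#' @examples
#' tr <- parse_newick("((a,b)x,c)r;")
#' n_tips(tr)
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply `text` or `file`")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  depth <- cumsum((chars <- strsplit(text, "")[[1L]]) == "(") -
    cumsum(chars == ")")
  if (any(depth < 0L) || tail(depth, 1L) != 0L) {
    pos <- if (any(depth < 0L)) which(depth < 0L)[1L] else length(chars)
    stop("malformed Newick: unbalanced parenthesis at position ", pos)
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("malformed Newick string: ", substr(text, 1, 60))
  as_cophy_tree(phy)
}

#' Convert an ape phylo object to a cophy_tree
#' @param phy an [ape::read.tree()] style `phylo` object (rooted, binary).
#' @return A [cophy_tree()].
#' @export
as_cophy_tree <- function(phy) {
  if (inherits(phy, "cophy_tree")) return(phy)
  if (!inherits(phy, "phylo")) stop("expected a 'phylo' or 'cophy_tree'")
  n <- length(phy$tip.label)
  if (n < 2L) stop("trees must have at least 2 tips; the root must bifurcate")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  N <- 2L * n - 1L
  if (phy$Nnode != n - 1L) {
    counts <- tabulate(phy$edge[, 1L], nbins = n + phy$Nnode)
    bad <- which(counts > 2L)[1L]
    stop("polytomy at internal node ",
         if (!is.null(phy$node.label) &&
             !is.na(phy$node.label[bad - n])) phy$node.label[bad - n] else bad)
  }
  parent <- integer(N)
  children <- matrix(0L, 2L, N)
  slot <- integer(N)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]; v <- phy$edge[e, 2L]
    parent[v] <- p
    slot[p] <- slot[p] + 1L
    if (slot[p] > 2L) stop("polytomy at internal node ", p)
    children[slot[p], p] <- v
  }
  lbl <- phy$node.label
  if (!is.null(lbl)) lbl[!nzchar(lbl)] <- NA_character_
  cophy_tree(parent, children, phy$tip.label, lbl)
}

#' Convert a cophy_tree to an ape phylo
#' @param x a [cophy_tree()].
#' @param ... unused.
#' @return A `phylo` object.
#' @method as.phylo cophy_tree
#' @export
as.phylo.cophy_tree <- function(x, ...) {
  n <- x$n_tips
  kids <- x$children
  edge <- matrix(0L, x$n_nodes - 1L, 2L)
  k <- 0L
  for (v in (n + 1L):x$n_nodes) {
    edge[k + 1L, ] <- c(v, kids[1L, v])
    edge[k + 2L, ] <- c(v, kids[2L, v])
    k <- k + 2L
  }
  phy <- list(edge = edge, tip.label = x$tip_label, Nnode = n - 1L)
  if (!all(is.na(x$node_label))) {
    nl <- x$node_label
    nl[is.na(nl)] <- ""
    phy$node.label <- nl
  }
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  phy
}

#' Serialize a tree to Newick
#' @param tree a [cophy_tree()].
#' @return A single Newick string (with trailing `;`).
#' @export
write_newick <- function(tree) {
  ape::write.tree(as.phylo.cophy_tree(tree))
}

#' @export
print.cophy_tree <- function(x, ...) {
  cat("<cophy_tree> ", x$n_tips, " tips, ", x$n_nodes, " nodes",
      if (inherits(x, "dated_cophy_tree")) ", dated" else "",
      "\n", sep = "")
  cat("  tips: ", paste(head(x$tip_label, 6L), collapse = ", "),
      if (x$n_tips > 6L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Number of tips / nodes
#' @param tree a [cophy_tree()].
#' @return Integer count.
#' @export
n_tips <- function(tree) tree$n_tips

#' @rdname n_tips
#' @export
n_nodes <- function(tree) tree$n_nodes

# resolve a node given as id or label to an integer id
resolve_node <- function(tree, x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (any(x < 1L | x > tree$n_nodes)) {
      stop("unknown node id ", x[which(x < 1L | x > tree$n_nodes)[1L]])
    }
    return(x)
  }
  out <- match(x, tree$tip_label)
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- match(x[miss], tree$node_label) + tree$n_tips
  }
  if (anyNA(out)) stop("unknown node label '", x[is.na(out)][1L], "'")
  out
}

# preorder node sequence (parents before children, left before right);
# preallocated explicit stack, linear time
preorder_nodes <- function(tree) {
  N <- tree$n_nodes
  out <- integer(N)
  stack <- integer(N)
  stack[1L] <- tree$root
  top <- 1L
  k <- 0L
  kids <- tree$children
  while (top > 0L) {
    v <- stack[top]
    top <- top - 1L
    k <- k + 1L
    out[k] <- v
    if (kids[1L, v] > 0L) {
      stack[top + 1L] <- kids[2L, v]
      stack[top + 2L] <- kids[1L, v]
      top <- top + 2L
    }
  }
  out
}

node_depths <- function(tree) {
  depth <- integer(tree$n_nodes)
  for (v in preorder_nodes(tree)) {
    if (v != tree$root) depth[v] <- depth[tree$parent[v]] + 1L
  }
  depth
}

#' Node levels
#'
#' The level of a node is its maximum distance from its descendant leaves:
#' leaves sit at level 0, an internal node at 1 plus the larger of its
#' children's levels. The tree height is the root's level, bounded between
#' `log2(n)` (balanced) and `n-1` (caterpillar).
#'
#' @param tree a [cophy_tree()].
#' @param node optional node id or label; if omitted, the full vector of
#'   levels (indexed by node id) is returned.
#' @return Integer level(s).
#' @export
#' @examples
#' node_level(parse_newick("((a,b)x,c)r;"), "r")
node_level <- function(tree, node = NULL) {
  lev <- integer(tree$n_nodes)
  for (v in rev(preorder_nodes(tree))) {
    if (tree$children[1L, v] > 0L) {
      lev[v] <- 1L + max(lev[tree$children[, v]])
    }
  }
  if (is.null(node)) lev else lev[resolve_node(tree, node)]
}

#' @rdname node_level
#' @export
tree_height <- function(tree) node_level(tree, tree$root)

#' Level profile g(i)
#'
#' Counts the nodes at each level of the tree: `g(0) = n` (all leaves),
#' and the counts sum to `2n-1`.
#'
#' @param tree a [cophy_tree()].
#' @return A tibble with columns `level` and `count`, one row per level
#'   `0..height`.
#' @export
level_profile <- function(tree) {
  lev <- node_level(tree)
  h <- max(lev)
  tibble::tibble(level = 0:h,
                 count = as.integer(tabulate(lev + 1L, nbins = h + 1L)))
}

#' Ancestry queries
#'
#' `is_ancestor()` tests (by default strict) ancestry of `u` over `v`;
#' `lca_node()` returns the least common ancestor; `edge_distance()` counts
#' edges on the unique path from an ancestor to a descendant.
#'
#' @param tree a [cophy_tree()].
#' @param u,v node ids or labels.
#' @param strict if `TRUE` (default) a node is not its own ancestor.
#' @return `is_ancestor()` a logical; `lca_node()` a node id;
#'   `edge_distance()` an integer edge count.
#' @export
is_ancestor <- function(tree, u, v, strict = TRUE) {
  u <- resolve_node(tree, u); v <- resolve_node(tree, v)
  if (u == v) return(!strict)
  while (v != tree$root) {
    v <- tree$parent[v]
    if (v == u) return(TRUE)
  }
  FALSE
}

#' @rdname is_ancestor
#' @export
lca_node <- function(tree, u, v) {
  u <- resolve_node(tree, u); v <- resolve_node(tree, v)
  anc <- u
  while (u != tree$root) {
    u <- tree$parent[u]
    anc <- c(anc, u)
  }
  while (!(v %in% anc)) v <- tree$parent[v]
  v
}

#' @rdname is_ancestor
#' @param anc,desc node ids or labels; `anc` must be ancestral to (or equal
#'   to) `desc`.
#' @export
edge_distance <- function(tree, anc, desc) {
  anc <- resolve_node(tree, anc); desc <- resolve_node(tree, desc)
  d <- 0L
  while (desc != anc) {
    if (desc == tree$root) {
      stop("nodes are incomparable: no ancestor-descendant path")
    }
    desc <- tree$parent[desc]
    d <- d + 1L
  }
  d
}

# flat arrays handed to the C++ routines (0 sentinels, 1-based ids)
tree_arrays <- function(tree) {
  rk <- if (!is.null(tree$rank)) tree$rank else rep(1L, tree$n_nodes)
  list(parent = tree$parent,
       left = tree$children[1L, ],
       right = tree$children[2L, ],
       rank = rk)
}
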