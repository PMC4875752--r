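#' Unfiltered full-table dynamic programme
#'
#' Correctness reference for [solve_dtr()]: fills the dense
#' `(2n_p - 1) x (2n_h - 1)` cost matrix, cell `(p, h)` holding the minimum
#' cost of embedding the parasite subtree of `p` with `p` placed on host
#' node `h`, minimised over every pair of child placements. Shares the exact
#' event semantics (one `classify_event`) with the filtered solver; it is
#' deliberately naive and only meant for small instances.
#'
#' @param tg a [tanglegram()].
#' @param costs an [event_costs()] scheme.
#' @return A list: `optimum`, the cost `table` (parasite nodes x host nodes,
#'   `Inf` marks unreachable cells), `populated` (finite cell count) and
#'   `cells` (the full matrix dimension product).
#' @export
dtr_full_table <- function(tg, costs = event_costs()) {
  costs <- as_event_costs(costs)
  ha <- tree_arrays(tg$host)
  pa <- tree_arrays(tg$parasite)
  res <- .full_table_cpp(ha$parent, ha$left, ha$right, ha$rank,
                         pa$parent, pa$left, pa$right, tg$phi,
                         unclass(costs))
  dimnames(res$table) <- list(parasite = seq_len(tg$parasite$n_nodes),
                              host = seq_len(tg$host$n_nodes))
  res$cells <- as.double(tg$parasite$n_nodes) * tg$host$n_nodes
  res
}

#' Exhaustive reconciliation enumerator
#'
#' Second, independent correctness reference: enumerates every assignment of
#' the internal parasite nodes to host nodes (leaves are fixed by phi), sums
#' the induced per-node event costs, skips infeasible assignments, and
#' returns the minimum. Guarded against blow-up.
#'
#' @param tg a [tanglegram()].
#' @param costs an [event_costs()] scheme.
#' @param max_internal,max_host_nodes enumeration guards (defaults: 5
#'   internal parasite nodes, 11 host nodes).
#' @return The minimum reconciliation cost (`Inf` if no feasible map, which
#'   cannot occur for finite switch and loss costs).
#' @export
dtr_brute_force <- function(tg, costs = event_costs(), max_internal = 5L,
                            max_host_nodes = 11L) {
  costs <- as_event_costs(costs)
  if (tg$parasite$n_tips - 1L > max_internal ||
      tg$host$n_nodes > max_host_nodes) {
    stop("instance too large for exhaustive enumeration (",
         tg$parasite$n_tips - 1L, " internal parasite nodes, ",
         tg$host$n_nodes, " host nodes)")
  }
  ha <- tree_arrays(tg$host)
  pa <- tree_arrays(tg$parasite)
  .brute_force_cpp(ha$parent, ha$left, ha$right, ha$rank,
                   pa$parent, pa$left, pa$right, tg$phi, unclass(costs))
}
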