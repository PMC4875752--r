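# --- minimal exact big-integer arithmetic (little-endian decimal digits) ---
# only what the site-count recurrence needs: add, subtract a small constant,
# compare, print; no installed bignum dependency required at this scale
.big <- function(x) {
  if (x == 0) return(0L)
  d <- integer(0)
  while (x > 0) { d <- c(d, x %% 10L); x <- x %/% 10L }
  d
}
.big_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, integer(n - length(a))); b <- c(b, integer(n - length(b)))
  s <- a + b; carry <- 0L
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% 10L
    s[i] <- s[i] %% 10L
  }
  if (carry > 0L) s <- c(s, .big(carry))
  s
}
.big_sub_small <- function(a, k) {     # a - k, assuming a >= k >= 0
  i <- 1L
  a[1L] <- a[1L] - as.integer(k)
  while (a[i] < 0L) {
    borrow <- (-a[i] + 9L) %/% 10L
    a[i] <- a[i] + 10L * borrow
    a[i + 1L] <- a[i + 1L] - borrow
    i <- i + 1L
  }
  while (length(a) > 1L && a[length(a)] == 0L) a <- a[-length(a)]
  a
}
.big_str <- function(a) paste(rev(a), collapse = "")

#' Per-level retained-site bound a_i
#'
#' The maximum number of mapping sites a single parasite node at level `i`
#' can retain once the codivergence/duplication and most-recent-host-switch
#' filters are applied. Two equivalent forms: the additive recurrence
#' `a_0 = 1, a_1 = 3, a_i = a_{i-1} + a_{i-1} + 2`, and its closed form
#' `a_i = 5 * 2^(i-1) - 2` (for `i >= 1`). `a_1` is 3 rather than 4 because
#' at level one both host-switch candidates already sit on host leaves.
#'
#' @param i level(s), non-negative integers.
#' @param form `"closed"` or `"recurrence"`.
#' @return `a_sites()`: numeric (exact up to `i = 51`); `a_sites_exact()`:
#'   the exact value as a decimal string, any `i`.
#' @export
#' @examples
#' a_sites(0:3)
a_sites <- function(i, form = c("closed", "recurrence")) {
  form <- match.arg(form)
  if (any(i < 0)) stop("level i must be non-negative")
  if (form == "closed") {
    ifelse(i == 0, 1, 5 * 2^(i - 1) - 2)
  } else {
    vapply(i, function(k) {
      if (k == 0) return(1)
      a <- 3
      for (j in seq_len(k - 1L) + 1L) a <- a + a + 2
      a
    }, 0)
  }
}

#' @rdname a_sites
#' @export
a_sites_exact <- function(i, form = c("closed", "recurrence")) {
  form <- match.arg(form)
  if (any(i < 0)) stop("level i must be non-negative")
  one <- function(k) {
    if (k == 0) return("1")
    if (form == "recurrence") {
      a <- .big(3)
      if (k > 1) for (j in 2:k) a <- .big_add(.big_add(a, a), .big(2))
      return(.big_str(a))
    }
    p <- .big(1)                       # 2^(k-1) by doubling
    if (k > 1) for (j in 2:k) p <- .big_add(p, p)
    five_p <- .big_add(.big_add(p, p), .big_add(.big_add(p, p), p))
    .big_str(.big_sub_small(five_p, 2L))
  }
  vapply(i, one, "")
}

#' Per-level site budget f(i)
#'
#' The piecewise site budget for a parasite node at level `i` against a host
#' node budget `n`: 1 at level 0, then the smaller of the level bound and
#' `n`. `version = "current"` uses the additive bound `5 * 2^(i-1) - 2`;
#' `version = "previous"` the earlier multiplicative bound
#' `min(3^(2^i - 1), n)`. The current budget never exceeds the previous one.
#'
#' @param i level(s) (>= 0).
#' @param n host node budget (>= 1).
#' @param version `"current"` or `"previous"`.
#' @return Numeric site budget(s).
#' @export
#' @examples
#' f_sites(2, 1000)               # 8
#' f_sites(2, 1000, version = "previous")  # 27
f_sites <- function(i, n, version = c("current", "previous")) {
  version <- match.arg(version)
  if (any(i < 0) || n < 1) stop("need i >= 0 and n >= 1")
  if (version == "current") {
    ifelse(i == 0, 1, pmin(ifelse(i > 60, Inf, 5 * 2^(pmax(i, 1) - 1) - 2),
                           n))
  } else {
    expo <- 2^pmin(i, 60) - 1
    ifelse(i == 0, 1, pmin(ifelse(expo * log(3) > log(n) + 1, Inf, 3^expo),
                           n))
  }
}

#' Level threshold where the site bound saturates
#'
#' The level `floor(lg(n + 2)) - 1` below which `5 * 2^(i-1) - 2 < n`
#' holds, i.e. where the per-node site bound is still below the host node
#' budget; at and above it, `f(i)` saturates at `n`.
#'
#' @param n node budget (>= 1).
#' @return Integer threshold.
#' @export
level_threshold <- function(n) {
  if (any(n < 1)) stop("n must be >= 1")
  vapply(n, function(m) {
    k <- as.integer(floor(log2(m + 2)))
    if (2^(k + 1) <= m + 2) k <- k + 1L
    if (2^k > m + 2) k <- k - 1L
    k - 1L
  }, 1L)
}

#' Expected internal-node counts per level, g(i)
#'
#' The expected number of internal nodes at level `i >= 1` of an `n`-leaf
#' tree: `2^(i-1) n / 3^i` under the Yule model, `3^(i-1) n / 4^i` under the
#' Uniform (PDA) model. Level 0 (the leaves) is handled separately as `n`.
#'
#' @param model `"yule"` or `"uniform"`.
#' @param i level(s), >= 1.
#' @param n number of leaves (>= 2).
#' @return Expected count(s).
#' @export
#' @examples
#' g_level("yule", 1, 300)     # 100
#' g_level("uniform", 1, 400)  # 100
g_level <- function(model = c("yule", "uniform"), i, n) {
  model <- match.arg(model)
  if (any(i < 1)) stop("g(i) is defined for levels i >= 1; level 0 holds the n leaves")
  if (n < 2) stop("n must be >= 2")
  if (model == "yule") 2^(i - 1) * n / 3^i else 3^(i - 1) * n / 4^i
}

geom_sum <- function(r, a, b) {         # sum_{i=a}^{b} r^i, b >= a
  if (b < a) return(0)
  (r^a - r^(b + 1)) / (1 - r)
}

#' Model space bound for the dated tree reconciliation table
#'
#' Evaluates the finite-sum space bound obtained by combining the per-node
#' budget `f(i)` with the expected level profile `g(i)`: `n` sites for the
#' leaves, the additive bound below the saturation threshold, and `n` sites
#' per node above it, with the height term running to the worst-case `n - 1`.
#' Asymptotically the Yule sum collapses to `O(n^(1 + 2 - lg 3)) ~ O(n^1.42)`
#' and the Uniform sum to `O(n^(lg 3)) ~ O(n^1.58)`;
#' `space_exponent()` returns those exponents.
#'
#' @param model `"yule"` or `"uniform"`.
#' @param n leaves (>= 2).
#' @param rounded for `space_exponent()`: return the two-decimal rounding
#'   (1.42 / 1.58) instead of the exact `3 - lg 3` / `lg 3`.
#' @return The bound value (sites).
#' @export
space_bound <- function(model = c("yule", "uniform"), n) {
  model <- match.arg(model)
  if (n < 2) stop("n must be >= 2")
  K <- level_threshold(n) + 1L          # = floor(lg(n + 2))
  if (model == "yule") {
    low <- 5 / 4 * geom_sum(4 / 3, 1, K - 1) - geom_sum(2 / 3, 1, K - 1)
    high <- (n / 2) * geom_sum(2 / 3, K, n - 1)
  } else {
    low <- 5 / 6 * geom_sum(3 / 2, 1, K - 1) -
      (2 / 3) * geom_sum(3 / 4, 1, K - 1)
    high <- (n / 3) * geom_sum(3 / 4, K, n - 1)
  }
  n + n * (low + high)
}

#' @rdname space_bound
#' @export
space_exponent <- function(model = c("yule", "uniform"), rounded = TRUE) {
  model <- match.arg(model)
  e <- if (model == "yule") 1 + 2 - log2(3) else log2(3)
  if (rounded) round(e, 2) else e
}

#' Fraction of tree space occupied by realistic tree heights
#'
#' Compares the band of tree heights observed for Yule/Uniform trees
#' (empirically bounded by the curves `4.11 n^0.23` and `4.68 n^0.41`)
#' against the full range of binary-tree heights (`lg n` to `n - 1`), by
#' integrating both bands over a taxon range via closed-form
#' antiderivatives. Over `[10, 2500]` the realistic band is about 4.99% of
#' the whole; the fraction decreases towards 0 as the upper limit grows.
#'
#' @param lo,hi integration limits in taxa, `2 <= lo < hi`.
#' @return A list: `s_star` (realistic band area), `s_t` (total band area),
#'   `fraction` (= `s_star / s_t`).
#' @export
#' @examples
#' tree_space_fraction(10, 2500)
tree_space_fraction <- function(lo, hi) {
  if (lo < 2 || lo >= hi) stop("need 2 <= lo < hi")
  F_star <- function(x) 4.68 * x^1.41 / 1.41 - 4.11 * x^1.23 / 1.23
  F_t <- function(x) (x^2 / 2 - x) - (x * log(x) - x) / log(2)
  s_star <- F_star(hi) - F_star(lo)
  s_t <- F_t(hi) - F_t(lo)
  list(s_star = s_star, s_t = s_t, fraction = s_star / s_t)
}

#' Memory arithmetic for the dynamic-programming table
#'
#' Converts table layouts into mapping-site and byte counts: the dense
#' matrix keeps `(2n-1)(2m-1)` sites for `n` host and `m` parasite leaves;
#' the sublinear (worst-case Uniform) layout keeps
#' `round((2m-1) * (2n-1)^0.58)`. Each stored mapping site occupies 36 bytes
#' (28 bytes of members plus two 32-bit words of object header). Binary
#' units are used throughout (1 KB = 1024 bytes).
#'
#' @param n_host_leaves,n_parasite_leaves leaves per tree (>= 2).
#' @param instances number of parallel problem instances (>= 1).
#' @param layout `"matrix"` or `"sublinear"`.
#' @return A list: `sites` (per instance), `bytes` (total across instances),
#'   and `pretty` (human-readable size).
#' @export
#' @examples
#' memory_model(200, 300, layout = "matrix")$sites     # 239001
#' memory_model(200, 300, layout = "sublinear")$sites  # 19319
memory_model <- function(n_host_leaves, n_parasite_leaves, instances = 1,
                         layout = c("matrix", "sublinear")) {
  layout <- match.arg(layout)
  if (n_host_leaves < 2 || n_parasite_leaves < 2 || instances < 1) {
    stop("need at least 2 leaves per tree and 1 instance")
  }
  nh <- 2 * n_host_leaves - 1
  np <- 2 * n_parasite_leaves - 1
  sites <- if (layout == "matrix") nh * np else round(np * nh^0.58)
  bytes <- 36 * sites * instances
  list(sites = sites, bytes = bytes, pretty = format_bytes(bytes))
}

#' @rdname memory_model
#' @param bytes a byte count.
#' @param unit one of `"B"`, `"KB"`, `"MB"`, `"GB"`, `"TB"` to force a unit,
#'   or `NULL` to pick the largest unit with a value >= 1.
#' @param digits rounding for the value.
#' @export
format_bytes <- function(bytes, unit = NULL, digits = 0) {
  units <- c(B = 1, KB = 1024, MB = 1024^2, GB = 1024^3, TB = 1024^4)
  if (is.null(unit)) {
    unit <- names(units)[max(1L, findInterval(bytes, unclass(units)))]
  }
  unit <- match.arg(unit, names(units))
  paste0(round(bytes / units[[unit]], digits), " ", unit)
}

#' Expected per-node site count and time exponent
#'
#' Spreading the total expected storage uniformly over the `O(n)` parasite
#' nodes gives an average of `n^0.42` retained sites per node for Yule
#' systems and `n^0.58` for Uniform systems; with the `n m^2` running time
#' of pairwise site combination this yields expected time exponents 1.84
#' and 2.17.
#'
#' @param model `"yule"` or `"uniform"`.
#' @param n leaves (>= 2).
#' @return A list: `m_expected`, `time_exponent`.
#' @export
expected_complexities <- function(model = c("yule", "uniform"), n) {
  model <- match.arg(model)
  if (n < 2) stop("n must be >= 2")
  if (model == "yule") {
    list(m_expected = n^0.42, time_exponent = 1.84)
  } else {
    list(m_expected = n^0.58, time_exponent = 2.17)
  }
}
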