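#' Log-spaced size grid for space profiling
#'
#' @param lo,hi taxon range (defaults 10 to 2500).
#' @param k number of sizes (default 25); duplicates after rounding are
#'   dropped.
#' @return An integer vector of sizes.
#' @export
profile_sizes <- function(lo = 10, hi = 2500, k = 25) {
  unique(round(10^seq(log10(lo), log10(hi), length.out = k)))
}

#' Empirical space profile of the filtered solver
#'
#' Simulates tanglegrams over a size grid, solves each with [solve_dtr()],
#' and records the number of retained mapping sites against the dense-matrix
#' cell count — the measurements behind the observed sub-quadratic
#' mapping-site growth. Replicate `r` of size index `s` draws its RNG stream
#' deterministically from `(seed, s, r)`.
#'
#' @param sizes taxa per tree, e.g. [profile_sizes()].
#' @param model `"yule"` or `"uniform"`.
#' @param reps replicates per size.
#' @param seed integer seed for the whole profile.
#' @param costs an [event_costs()] scheme.
#' @return A tibble: `model`, `n`, `replicate`, `retained_sites`,
#'   `full_cells`.
#' @export
#' @examples
#' profile_space(c(10, 20, 40), "yule", reps = 3, seed = 1)
profile_space <- function(sizes, model = c("yule", "uniform"), reps = 20,
                          seed = 1L, costs = event_costs()) {
  model <- match.arg(model)
  rows <- vector("list", length(sizes) * reps)
  k <- 0L
  for (s in seq_along(sizes)) {
    for (r in seq_len(reps)) {
      tg <- sim_tanglegram(sizes[s], model,
                           seed = replicate_seed(seed, 1000L * s + r))
      rec <- solve_dtr(tg, costs)
      k <- k + 1L
      rows[[k]] <- tibble::tibble(model = model, n = sizes[s],
                                  replicate = r,
                                  retained_sites = rec$retained_sites,
                                  full_cells = rec$full_cells)
    }
  }
  dplyr::bind_rows(rows)
}

#' Fit the observed space scaling
#'
#' Reduces a space profile to per-size medians (matching how replicate space
#' measurements are summarised before curve fitting) and fits the power law
#' `l(n) = a * n^b` with [power_law_fit()]. The default is nonlinear least
#' squares on the original scale; `scale = "log"` gives the classical
#' log-log regression, which weights every decade of tree sizes equally
#' (on Yule profiles it lands next to published constants near
#' `5.3 n^1.2`, while emphasising the saturation-driven steepening of
#' Uniform profiles).
#'
#' @param profile output of [profile_space()].
#' @param scale passed to [power_law_fit()]; default `"original"`.
#' @return A [power_law_fit()].
#' @export
fit_space_scaling <- function(profile, scale = "original") {
  med <- dplyr::summarise(dplyr::group_by(profile, .data$n),
                          space = stats::median(.data$retained_sites),
                          .groups = "drop")
  power_law_fit(med, scale = scale)
}
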