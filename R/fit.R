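#' Power-law least-squares fit l(n) = a * n^b
#'
#' Fits a power law to observed space requirements. With
#' `scale = "original"` (default) the fit is nonlinear least squares on the
#' raw values ([minpack.lm::nlsLM()], Levenberg-Marquardt), initialised
#' from the log-log linear regression; with `scale = "log"` it is the
#' ordinary least-squares line on the log-log scale (the classical
#' power-law fit, which weights every decade of `n` equally). `r_squared`
#' is `1 - SS_res / SS_tot` computed on the original (not log) scale in
#' both cases. For space profiles of the dated tree reconciliation table
#' the exponent `b` is expected to lie between 1 (each parasite node keeps
#' at least one site) and 2 (the dense matrix).
#'
#' @param data a data frame of observations, typically per-size medians.
#' @param size,value columns of `data` holding the problem size `n` and the
#'   observed quantity (tidy-eval; defaults `n` and `space`).
#' @param scale `"original"` or `"log"` (see Details).
#' @return A `power_law_fit` with fields `a`, `b`, `r_squared`, `n_points`;
#'   see [tidy.power_law_fit()], `glance()`, `predict()` and `autoplot()`
#'   methods.
#' @export
#' @examples
#' d <- tibble::tibble(n = c(10, 50, 100, 500, 1000), space = 2 * n^1.5)
#' power_law_fit(d)
power_law_fit <- function(data, size = n, value = space,
                          scale = c("original", "log")) {
  scale <- match.arg(scale)
  n <- rlang::eval_tidy(rlang::enquo(size), data)
  y <- rlang::eval_tidy(rlang::enquo(value), data)
  if (length(n) != length(y) || anyNA(n) || anyNA(y)) {
    stop("size and value must be complete and of equal length")
  }
  if (length(unique(n)) < 3L) {
    stop("need at least 3 distinct sizes to fit a power law")
  }
  if (any(y <= 0) || any(n <= 0)) stop("sizes and values must be positive")
  init <- stats::lm(log(y) ~ log(n))
  if (scale == "log") {
    a <- exp(coef(init)[[1L]]); b <- coef(init)[[2L]]
  } else {
    start <- list(a = exp(coef(init)[[1L]]), b = coef(init)[[2L]])
    df <- data.frame(n = n, y = y)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * n^b, data = df, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {        # degenerate surface: keep the log-log solution
      a <- start$a; b <- start$b
    } else {
      a <- coef(fit)[["a"]]; b <- coef(fit)[["b"]]
    }
  }
  ss_res <- sum((y - a * n^b)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(a = a, b = b,
                 r_squared = 1 - ss_res / ss_tot,
                 n_points = length(n), scale = scale,
                 data = tibble::tibble(n = n, space = y)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> l(n) = %.3g * n^%.3g  (R^2 = %.4f, %d points)\n",
              x$a, x$b, x$r_squared, x$n_points))
  invisible(x)
}

#' Tidiers for power-law fits
#' @param x,object a `power_law_fit`.
#' @param ... unused.
#' @return `tidy()`: one row per parameter; `glance()`: a one-row summary.
#' @method tidy power_law_fit
#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @rdname tidy.power_law_fit
#' @method glance power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, r_squared = x$r_squared,
                 n_points = x$n_points)
}

#' @rdname tidy.power_law_fit
#' @param newdata optional data frame with a column `n`.
#' @export
predict.power_law_fit <- function(object, newdata = NULL, ...) {
  n <- if (is.null(newdata)) object$data$n else newdata$n
  object$a * n^object$b
}

#' @rdname tidy.power_law_fit
#' @method autoplot power_law_fit
#' @export
autoplot.power_law_fit <- function(object, ...) {
  grid <- tibble::tibble(
    n = exp(seq(log(min(object$data$n)), log(max(object$data$n)),
                length.out = 200)))
  grid$space <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$n, y = .data$space)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "taxa per tree (n)", y = "retained mapping sites",
                  subtitle = sprintf("l(n) = %.2f n^%.2f, R^2 = %.3f",
                                     object$a, object$b, object$r_squared))
}
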