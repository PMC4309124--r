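#' Dispersion statistics of a frequency vector
#'
#' Sample mean, variance, dispersion coefficient and the normalized
#' dispersion (u-test) statistic of a count frequency distribution.
#' With `n` cells, `z` total events, sample mean \eqn{\bar y} and sample
#' variance \eqn{s_y^2} (denominator `n - 1`), the dispersion coefficient is
#' \eqn{d = s_y^2 / \bar y} and
#' \deqn{u = (d - 1) \sqrt{(n - 1) / (2 (1 - 1/z))}.}
#' Under an equidispersed (Poisson) law `u` is approximately standard
#' normal; `|u| > 2` flags over- (under-) dispersion, the rule used to
#' decide whether a compound response family is needed.
#'
#' @param x a frequency vector (element `k+1` = cells with `k` events) or a
#'   [TestSample-class].
#' @return an object of class `"uTest"`: a list with `n`, `z`, `ybar`, `var`,
#'   `d`, `u` and a dispersion `verdict`.
#' @examples
#' uTest(c(1712, 96, 3))  # 1811 cells scored, u = 0.092
#' @export
uTest <- function(x) {
  if (is(x, "TestSample")) x <- x@freq
  if (any(x < 0) || sum(x) < 2)
    stop("need a nonnegative frequency vector with at least two cells")
  k <- seq_along(x) - 1
  n <- sum(x)
  z <- sum(k * x)
  if (z <= 1)
    stop("u statistic undefined: fewer than two events in the sample")
  ybar <- z / n
  s2 <- (sum(k^2 * x) - n * ybar^2) / (n - 1)
  d <- s2 / ybar
  u <- (d - 1) * sqrt((n - 1) / (2 * (1 - 1 / z)))
  verdict <- if (u > 2) "overdispersed" else if (u < -2) "underdispersed"
    else "equidispersed"
  structure(list(n = n, z = z, ybar = ybar, var = s2, d = d, u = u,
                 verdict = verdict), class = "uTest")
}

#' @export
print.uTest <- function(x, ...) {
  cat(sprintf("u-test: n = %d cells, z = %d events\n", x$n, x$z))
  cat(sprintf("  ybar = %.3f, d = %.3f, u = %.3f -> %s\n",
              x$ybar, x$d, x$u, x$verdict))
  invisible(x)
}
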