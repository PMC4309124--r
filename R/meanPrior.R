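## Delta-method mean prior: distribution of (mu, delta) at a candidate dose.

## beta-block of the covariance (drops the delta row if present)
.betaCov <- function(fit) {
  p <- length(fit@curve@beta)
  fit@cov[seq_len(p), seq_len(p), drop = FALSE]
}

#' Mean and variance of the aberration yield at candidate doses
#'
#' The delta-method first two moments of \eqn{\mu | x}: mean
#' \eqn{f(x, \hat\beta)} and variance
#' \eqn{v(x, \hat\beta) = \nabla f \cdot \hat\Sigma \cdot \nabla f^t}.
#'
#' @param fit a [FittedCalibration-class].
#' @param x numeric vector of doses (Gy).
#' @return list with numeric vectors `mean` and `var`.
#' @export
meanVariance <- function(fit, x) {
  g <- curveGradient(fit@curve, x)
  list(mean = curveMean(fit@curve, x),
       var = rowSums((g %*% .betaCov(fit)) * g))
}

#' Mean prior parameters at candidate doses
#'
#' The prior for \eqn{\mu} at dose `x` propagating the calibration
#' uncertainty: either the delta-method normal \eqn{N(f, v)}, or the gamma
#' with the same mean and variance (shape \eqn{f^2/v}, rate \eqn{f/v}),
#' used when the normal would put appreciable mass on negative yields.
#'
#' @inheritParams meanVariance
#' @param kind `"normal"` or `"gamma"`.
#' @return data.frame with columns `x`, `mean`, `var` and, for the gamma
#'   kind, `shape` and `rate`.
#' @export
meanPrior <- function(fit, x, kind = c("normal", "gamma")) {
  kind <- match.arg(kind)
  mv <- meanVariance(fit, x)
  if (any(mv$var <= 0))
    stop("nonpositive delta-method variance (defective information matrix)")
  out <- data.frame(x = x, mean = mv$mean, var = mv$var)
  if (kind == "gamma") {
    out$shape <- mv$mean^2 / mv$var
    out$rate <- mv$mean / mv$var
  }
  out
}

#' Bivariate mean prior for compound families
#'
#' The delta-method bivariate normal for \eqn{(\mu, \delta) | x} used by the
#' complete model: mean \eqn{(f(x,\hat\beta), \hat\delta)} and covariance
#' \eqn{\nabla \hat\Sigma_\Theta \nabla^t} with the gradient rows
#' \eqn{(\partial f/\partial\beta, 0)} and \eqn{(0, \ldots, 0, 1)}.
#'
#' @inheritParams meanVariance
#' @return list with `mean` (length-2 per dose, as a 2-column matrix) and
#'   `cov` (2 x 2 x length(x) array).
#' @export
bivariatePrior <- function(fit, x) {
  if (fit@family == "poisson")
    stop("the bivariate prior is defined for compound families only")
  p <- length(fit@curve@beta)
  if (ncol(fit@cov) != p + 1L)
    stop("fit has no delta row in its covariance")
  g <- curveGradient(fit@curve, x)
  Sbb <- .betaCov(fit)
  Sbd <- fit@cov[seq_len(p), p + 1L]
  Sdd <- fit@cov[p + 1L, p + 1L]
  v <- rowSums((g %*% Sbb) * g)
  cmd <- as.numeric(g %*% Sbd)
  covArr <- array(0, c(2, 2, length(x)))
  covArr[1, 1, ] <- v
  covArr[1, 2, ] <- covArr[2, 1, ] <- cmd
  covArr[2, 2, ] <- Sdd
  list(mean = cbind(mu = curveMean(fit@curve, x), delta = fit@delta),
       cov = covArr)
}

## family-specific admissibility criterion for the normal mean prior:
## the mixed normal predictive is a (compound) Hermite only while the
## implied counting dispersion stays <= 2.
.normalCriterion <- function(fit, m, x) {
  mv <- meanVariance(fit, x)
  f <- mv$mean; v <- mv$var; d <- fit@delta
  switch(fit@family,
    poisson = f - m * v,
    neymanA = f * (d - 1) - m * v,
    negbin = f * (d - 1) - m * v * log(d),
    hermite = 2 * f * (d - 1) - m * v)
}

#' Largest dose at which the normal mean prior is admissible
#'
#' Mixing the (compound) Poisson test likelihood with a normal mean prior
#' yields a (compound) Hermite predictive only while the implied Hermite
#' dispersion does not exceed 2, i.e. while the family-specific inequality
#' holds: \eqn{f \ge m v} (Poisson), \eqn{f(\delta-1) \ge m v} (Neyman A),
#' \eqn{f(\delta-1) \ge m v \log\delta} (negative binomial),
#' \eqn{2 f(\delta-1) \ge m v} (Hermite). Returns the largest `x` such that
#' the inequality holds throughout `[0, x]`, searching up to three times
#' the calibration dose range by root bracketing.
#'
#' @param fit a [FittedCalibration-class].
#' @param m number of cells scored in the test sample.
#' @param tol root-finding tolerance (Gy).
#' @return the bound in Gy; 0 (with a warning) if the inequality already
#'   fails as \eqn{x \to 0^+}, in which case the gamma mean prior must be
#'   used.
#' @examples
#' fit <- fitCalibration(dropDose(exampleCalibration("dicentrics"), 1.5),
#'                       "poisson", "linquad0")
#' normalValidityBound(fit, m = 1811)
#' @export
normalValidityBound <- function(fit, m, tol = 1e-6) {
  if (m < 1) stop("m must be >= 1")
  hi <- 3 * max(fit@doseRange)
  xs <- seq(0, hi, length.out = 4096)
  crit <- .normalCriterion(fit, m, xs)
  if (crit[2] < 0) {  # fails immediately above 0
    warning("normal mean prior inadmissible near 0; use the gamma prior")
    return(0)
  }
  bad <- which(crit < 0)
  if (!length(bad)) return(hi)  # holds on the whole search window
  i <- bad[1]
  uniroot(function(z) .normalCriterion(fit, m, z), c(xs[i - 1], xs[i]),
          tol = tol)$root
}

#' Minimum gamma shape of the mean prior over a dose range
#'
#' The shape parameter of the moment-matched gamma mean prior is
#' \eqn{f(x)^2 / v(x)}; large values certify that the gamma and normal
#' mean priors are practically indistinguishable. Returns the minimum over
#' `range` (grid search refined by [stats::optimize()]).
#'
#' @param fit a [FittedCalibration-class].
#' @param range length-2 numeric, the dose interval (Gy) to minimize over;
#'   a lower end of 0 is evaluated as the limit from above.
#' @return the minimal shape value.
#' @export
minGammaShape <- function(fit, range) {
  if (length(range) != 2L || diff(range) <= 0)
    stop("range must be an increasing dose interval")
  lo <- max(range[1], 1e-9)
  shape <- function(z) {
    mv <- meanVariance(fit, z)
    mv$mean^2 / mv$var
  }
  xs <- seq(lo, range[2], length.out = 2048)
  sh <- shape(xs)
  i <- which.min(sh)
  w <- c(max(lo, xs[max(1, i - 1)]), xs[min(length(xs), i + 1)])
  if (w[1] < w[2]) {
    op <- optimize(shape, w)
    min(op$objective, sh[i])
  } else sh[i]
}
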