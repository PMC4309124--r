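## Calibrative density: prior x predictive, normalized on a dose grid.

#' Construct a dose prior
#'
#' @param kind `"flat"` (improper uniform on `[0, Inf)`; admissible whenever
#'   the posterior integral converges, which the grid machinery audits),
#'   `"uniform"` (proper on `[min, max]`) or `"gamma"`.
#' @param min,max support of the uniform prior.
#' @param mean,sd moments of the gamma prior.
#' @return a [DosePrior-class].
#' @examples
#' dosePrior("uniform", 0, 2)
#' dosePrior("gamma", mean = 1.75, sd = 0.375)
#' @export
dosePrior <- function(kind = c("flat", "uniform", "gamma"), min = 0,
                      max = Inf, mean = NULL, sd = NULL) {
  kind <- match.arg(kind)
  par <- switch(kind, flat = numeric(0),
                uniform = c(min, max), gamma = c(mean, sd))
  new("DosePrior", kind = kind, par = as.numeric(par))
}

#' @describeIn dosePrior prior density at doses `x` (the flat prior is the
#'   constant 1).
#' @param prior a `DosePrior`.
#' @param x doses (Gy).
#' @param log return the log density.
#' @export
priorDensity <- function(prior, x, log = FALSE) {
  ld <- switch(prior@kind,
    flat = rep(0, length(x)),
    uniform = ifelse(x >= prior@par[1] & x <= prior@par[2],
                     -base::log(prior@par[2] - prior@par[1]), -Inf),
    gamma = {
      sh <- (prior@par[1] / prior@par[2])^2
      dgamma(x, shape = sh, rate = sh / prior@par[1], log = TRUE)
    })
  if (log) ld else exp(ld)
}

setMethod("show", "DosePrior", function(object) {
  cat("DosePrior:", switch(object@kind,
    flat = "improper uniform on [0, Inf)",
    uniform = sprintf("uniform(%g, %g)", object@par[1], object@par[2]),
    gamma = sprintf("gamma(mean %g, sd %g)", object@par[1],
                    object@par[2])), "\n")
  invisible(object)
})

## mode (quadratic refinement), moments and equal-tail interval of a
## normalized gridded density
.summarizeDensity <- function(x, d, level = 0.95) {
  i <- which.max(d)
  mode <- x[i]
  if (i > 1 && i < length(x)) {
    den <- d[i - 1] - 2 * d[i] + d[i + 1]
    if (den < 0)
      mode <- x[i] + 0.5 * (x[i + 1] - x[i]) * (d[i - 1] - d[i + 1]) / den
  }
  mn <- pracma::trapz(x, x * d)
  vr <- pracma::trapz(x, x^2 * d) - mn^2
  cdf <- .cumtrapz(x, d)
  cdf <- cdf / cdf[length(cdf)]
  al <- (1 - level) / 2
  keep <- c(TRUE, diff(cdf) > 0)  # strictly increasing part for inversion
  ci <- approx(cdf[keep], x[keep], c(al, 1 - al), rule = 2)$y
  ## multimodality flag: another local max within 1% of the global one
  dm <- diff(d)
  turns <- which(dm[-1] < 0 & dm[-length(dm)] > 0) + 1
  multi <- sum(d[turns] > 0.01 * d[i]) > 1
  list(mode = mode, mean = mn, sd = sqrt(max(vr, 0)),
       ci = ci, level = level, multimodal = multi)
}

#' Assemble a calibrative density from predictive values and a prior
#'
#' Normalizes \eqn{p(x) q_s(x)} on the grid by the trapezoid rule and
#' attaches summaries. This is the low-level constructor used by
#' [doseEstimate()]; `logq` may come from [predictiveProb()],
#' [predictiveProbComplete()] or any user-supplied likelihood.
#'
#' @param x increasing dose grid (Gy).
#' @param logq log predictive values \eqn{\log q_s(x)} on the grid.
#' @param prior a [DosePrior-class].
#' @param level credible level for the equal-tail interval.
#' @param method,meanPrior labels stored in the result.
#' @return a [CalibrativeDensity-class].
#' @export
calibrativeDensity <- function(x, logq, prior = dosePrior("flat"),
                               level = 0.95, method = "custom",
                               meanPrior = "gamma") {
  stopifnot(length(x) == length(logq), !is.unsorted(x))
  ld <- logq + priorDensity(prior, x, log = TRUE)
  if (all(!is.finite(ld)))
    stop("the posterior is identically zero on the grid")
  d <- exp(ld - max(ld, na.rm = TRUE))
  d[!is.finite(d)] <- 0
  tot <- pracma::trapz(x, d)
  if (tot <= 0) stop("the posterior has zero mass on the grid")
  d <- d / tot
  sm <- .summarizeDensity(x, d, level)
  if (sm$multimodal)
    warning("multimodal calibrative density; reporting the global mode")
  new("CalibrativeDensity", dose = x, density = d, prior = prior,
      method = method, meanPrior = meanPrior, summaries = sm)
}

## --- accessors and methods ----------------------------------------------

#' @describeIn calibrativeDensity the dose grid.
#' @param object a `CalibrativeDensity`.
#' @export
setMethod("doses", "CalibrativeDensity", function(object) object@dose)

#' Density values of a calibrative density
#' @param x a [CalibrativeDensity-class].
#' @export
densityValues <- function(x) x@density

#' @describeIn calibrativeDensity named list with `mode`, `mean`, `sd` and
#'   the equal-tail credible interval `ci` (recomputed when `level` differs
#'   from the stored one).
#' @export
setMethod("doseSummary", "CalibrativeDensity",
  function(object, level = 0.95) {
    sm <- object@summaries
    if (!isTRUE(all.equal(level, sm$level)))
      sm <- .summarizeDensity(object@dose, object@density, level)
    sm[c("mode", "mean", "sd", "ci", "level")]
  })

#' @export
as.data.frame.CalibrativeDensity <- function(x, ...) {
  data.frame(dose = x@dose, density = x@density)
}

setMethod("show", "CalibrativeDensity", function(object) {
  s <- object@summaries
  cat(sprintf("Calibrative dose density (%s model, %s mean prior)\n",
              object@method, object@meanPrior))
  cat(sprintf("  mode %.3f Gy, mean %.3f Gy, sd %.3f Gy\n",
              s$mode, s$mean, s$sd))
  cat(sprintf("  %g%% equal-tail interval: (%.3f, %.3f) Gy\n",
              100 * s$level, s$ci[1], s$ci[2]))
  invisible(object)
})

#' @export
setMethod("plot", signature(x = "CalibrativeDensity", y = "missing"),
  function(x, y, ...) {
    graphics::plot(x@dose, x@density, type = "l", xlab = "dose (Gy)",
                   ylab = "calibrative density", ...)
    graphics::abline(v = x@summaries$mode, lty = 3)
    invisible(x)
  })

#' Closed-form calibrative density for a linear curve and flat prior
#'
#' For the linear response \eqn{f(x,\beta) = \beta x} with Poisson
#' calibration data, the gamma mean prior has shape \eqn{\sum y_i} (the
#' total calibration aberrations) and rate \eqn{A/x} with
#' \eqn{A = \sum n_i x_i}, and the flat-prior calibrative density is
#' available analytically:
#' \deqn{f(x | \tilde y) = \frac{m^{s+1} A^{T-1}}{B(s+1, T-1)}
#'   \frac{x^s}{(A + m x)^{s+T}}, \qquad T = \sum y_i,}
#' with mode \eqn{s A / (m T)}, mean \eqn{(A/m) B(s+2, T-2)/B(s+1, T-1)}
#' (needs `T > 2`) and second moment \eqn{(A/m)^2 B(s+3,T-3)/B(s+1,T-1)}
#' (needs `T > 3`). The distribution function is evaluated numerically.
#'
#' @param s total aberrations in the test sample.
#' @param m cells scored in the test sample.
#' @param sumDoseCells \eqn{A = \sum_i n_i x_i}, the cell-weighted sum of
#'   calibration doses.
#' @param sumAberr \eqn{T = \sum y_i}, the total calibration aberrations.
#' @param level credible level of the reported equal-tail interval.
#' @return list of class `"linearCalibrative"` with `density` (vectorized
#'   function of dose), `cdf`, `mode`, `mean`, `sd` (NA when the moments do
#'   not exist) and `ci`.
#' @export
linearCalibrative <- function(s, m, sumDoseCells, sumAberr, level = 0.95) {
  A <- sumDoseCells; T <- sumAberr
  stopifnot(s >= 0, m >= 1, A > 0, T > 1)
  lc <- (s + 1) * base::log(m) + (T - 1) * base::log(A) - lbeta(s + 1, T - 1)
  dens <- function(x)
    ifelse(x < 0, 0,
           exp(lc + s * base::log(x) - (s + T) * base::log(A + m * x)))
  ## substitution u = m x / (A + m x) maps to a Beta(s+1, T-1) law
  cdf <- function(x) {
    u <- m * x / (A + m * x)
    stats::pbeta(u, s + 1, T - 1)
  }
  qtl <- function(p) {
    u <- stats::qbeta(p, s + 1, T - 1)
    A * u / (m * (1 - u))
  }
  mode <- s * A / (m * T)
  mn <- if (T > 2) (A / m) * exp(lbeta(s + 2, T - 2) - lbeta(s + 1, T - 1))
    else NA_real_
  e2 <- if (T > 3) (A / m)^2 * exp(lbeta(s + 3, T - 3) - lbeta(s + 1, T - 1))
    else NA_real_
  al <- (1 - level) / 2
  structure(list(density = dens, cdf = cdf, quantile = qtl, mode = mode,
                 mean = mn, sd = if (is.na(e2)) NA_real_
                   else sqrt(e2 - mn^2),
                 ci = qtl(c(al, 1 - al)), level = level, s = s, m = m,
                 A = A, T = T),
            class = "linearCalibrative")
}

#' @export
print.linearCalibrative <- function(x, ...) {
  cat("Closed-form calibrative density (linear curve, flat prior)\n")
  cat(sprintf("  mode %.3f Gy, mean %.3f Gy, sd %.3f Gy\n",
              x$mode, x$mean, x$sd))
  cat(sprintf("  %g%% equal-tail interval: (%.3f, %.3f) Gy\n",
              100 * x$level, x$ci[1], x$ci[2]))
  invisible(x)
}
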