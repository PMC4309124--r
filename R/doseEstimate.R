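#' Estimate the absorbed dose from a test sample
#'
#' The full inverse-regression pipeline: evaluates the predictive
#' probability \eqn{q_s(x)} of the test total under the fitted calibration
#' (Poisson closed form, simplified compound recursions, or the complete
#' two-parameter model by numerical integration), multiplies by the dose
#' prior, and normalizes on an adaptively chosen grid.
#'
#' @param fit a [FittedCalibration-class].
#' @param test a [TestSample-class].
#' @param prior a [DosePrior-class]; default improper uniform.
#' @param meanPrior `"auto"`, `"normal"` or `"gamma"`. `"auto"` uses the
#'   normal variant when the whole working grid lies below
#'   [normalValidityBound()] and the gamma variant otherwise (the two are
#'   practically indistinguishable whenever the minimal gamma shape is
#'   large, see [minGammaShape()]).
#' @param method `"auto"` (Poisson closed form for Poisson fits, simplified
#'   compound model otherwise), `"poisson"`, `"simplified"` or
#'   `"complete"`.
#' @param gridSize number of grid points (default 2001; 601 for the
#'   complete model, whose integrand is costly).
#' @param gridMax upper end of the initial dose grid (Gy); default 1.5
#'   times the calibration dose maximum, automatically extended while
#'   appreciable flat-prior posterior mass remains beyond the end (up to
#'   10 times the calibration maximum, then an error).
#' @param level credible level of the reported equal-tail interval.
#' @param nodes quadrature nodes per axis for the complete model.
#' @return a [CalibrativeDensity-class].
#' @examples
#' cd <- exampleCalibration("dicentrics")
#' fit <- fitCalibration(dropDose(cd, 1.5), "poisson", "linquad0")
#' ts <- TestSample(cellCounts(cd)[4, ])  # the held-out 1.5 Gy sample
#' doseEstimate(fit, ts)
#' @export
doseEstimate <- function(fit, test, prior = dosePrior("flat"),
                         meanPrior = c("auto", "normal", "gamma"),
                         method = c("auto", "poisson", "simplified",
                                    "complete"),
                         gridSize = NULL, gridMax = NULL, level = 0.95,
                         nodes = 48) {
  meanPrior <- match.arg(meanPrior)
  method <- match.arg(method)
  s <- totalAberrations(test)
  m <- cellCounts(test)
  if (method == "auto")
    method <- if (fit@family == "poisson") "poisson" else "simplified"
  if (method == "poisson" && fit@family != "poisson")
    stop("method 'poisson' requires a Poisson calibration fit")
  if (method %in% c("simplified", "complete") && fit@family == "poisson")
    stop("method '", method, "' requires a compound-family fit")
  if (is.null(gridSize)) gridSize <- if (method == "complete") 601 else 2001

  cap <- 10 * max(fit@doseRange)
  lo <- if (prior@kind == "uniform") max(0, prior@par[1]) else 0
  hi <- if (!is.null(gridMax)) gridMax
    else if (prior@kind == "uniform") prior@par[2]
    else 1.5 * max(fit@doseRange)
  extensible <- is.null(gridMax) && prior@kind != "uniform"

  ## pass 1: locate the posterior support with the always-valid gamma
  ## variant of the (simplified) predictive, extending the window while
  ## appreciable mass sits at its end
  repeat {
    xc <- seq(lo, hi, length.out = 512)
    ldc <- .qsLog(fit, s, m, xc, "gamma") +
      priorDensity(prior, xc, log = TRUE)
    rel <- exp(ldc - max(ldc[is.finite(ldc)]))
    rel[!is.finite(rel)] <- 0
    if (!extensible || rel[length(rel)] < 1e-10) break
    if (hi >= cap)
      stop("posterior tail mass persists beyond ", signif(cap, 4),
           " Gy; supply gridMax explicitly")
    hi <- min(2 * hi, cap)
  }
  supp <- range(xc[rel > 1e-12])

  bound <- if (meanPrior != "gamma")
    suppressWarnings(normalValidityBound(fit, m)) else Inf
  if (meanPrior == "auto")
    meanPrior <- if (bound >= hi) "normal" else "gamma"
  if (meanPrior == "normal") {
    if (bound <= lo)
      stop("normal mean prior inadmissible on the working range; ",
           "use meanPrior = 'gamma'")
    if (bound < hi) {
      if (supp[2] > bound)
        stop("posterior support exceeds the normal-prior validity bound ",
             "(", signif(bound, 4), " Gy); use meanPrior = 'gamma'")
      hi <- bound  # cap the grid where the Hermite representation is valid
    }
  }

  if (method == "complete") {
    ## restrict the expensive integration to the (expanded) support window
    w <- diff(supp)
    lo <- max(lo, supp[1] - 0.75 * w)
    hi <- min(hi, supp[2] + 0.75 * w)
  }

  x <- seq(lo, hi, length.out = gridSize)
  logq <- switch(method,
    complete = predictiveProbComplete(fit, test, x, nodes = nodes,
                                      log = TRUE),
    .qsLog(fit, s, m, x, meanPrior))
  cd <- calibrativeDensity(x, logq, prior, level, method, meanPrior)
  ## audit residual tail mass at the grid end (not applicable where the
  ## prior or the validity bound itself truncates the support)
  if (prior@kind != "uniform" && (meanPrior != "normal" || bound > hi)) {
    n <- length(x)
    tail <- pracma::trapz(x[(n - 10):n], cd@density[(n - 10):n])
    if (tail > 1e-4)
      warning("appreciable posterior mass at the grid end; ",
              "increase gridMax")
  }
  cd
}
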