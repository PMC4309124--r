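## S4 classes for the calibration / inverse-regression pipeline.

.families <- c("poisson", "hermite", "neymanA", "negbin")
.forms <- c("linear", "linquad0", "linquad")

#' Dose-response curve
#'
#' The mean number of aberrations per cell as a function of dose,
#' \eqn{f(x, \beta)}. Three functional forms are supported:
#' \describe{
#'   \item{`"linear"`}{\eqn{f = \beta_1 x}}
#'   \item{`"linquad0"`}{\eqn{f = \beta_2 x^2 + \beta_1 x} (linear-quadratic
#'     without intercept, the standard acute low-LET curve)}
#'   \item{`"linquad"`}{\eqn{f = G \beta_2 x^2 + \beta_1 x + \beta_0}
#'     (linear-quadratic with background intercept; `G` is the
#'     Lea-Catcheside dose-protraction factor applied to the quadratic
#'     term, 1 for acute exposure)}
#' }
#' All coefficients are constrained nonnegative, as required for aberration
#' yields.
#'
#' @slot form one of `"linear"`, `"linquad0"`, `"linquad"`.
#' @slot beta named coefficient vector (subset of `beta0`, `beta1`, `beta2`).
#' @slot G Lea-Catcheside protraction factor in `[0, 1]`.
#' @export
setClass("DoseResponseCurve",
  representation(form = "character", beta = "numeric", G = "numeric"))

setValidity("DoseResponseCurve", function(object) {
  if (length(object@form) != 1L || !object@form %in% .forms)
    return(sprintf("form must be one of: %s", paste(.forms, collapse = ", ")))
  want <- switch(object@form,
    linear = "beta1", linquad0 = c("beta1", "beta2"),
    linquad = c("beta0", "beta1", "beta2"))
  if (length(object@beta) != length(want) ||
      !identical(names(object@beta), want))
    return(sprintf("beta must be the named vector (%s)",
                   paste(want, collapse = ", ")))
  if (any(!is.finite(object@beta)) || any(object@beta < 0))
    return("all coefficients must be finite and nonnegative")
  if (length(object@G) != 1L || !is.finite(object@G) ||
      object@G < 0 || object@G > 1)
    return("G must be a single number in [0, 1]")
  TRUE
})

#' Count response model
#'
#' One of the four per-cell count distributions used for aberration scoring,
#' parametrized by the population mean `mu` and the dispersion index
#' `delta` (variance-to-mean ratio). The compound families arise as
#' Poisson-stopped sums: Neyman A with a Poisson generalizing law, negative
#' binomial with a logarithmic one, Hermite with a Bin(2, delta - 1) one.
#' `delta = 1` is the Poisson (equidispersed) case; the Hermite family
#' requires `delta <= 2`.
#'
#' @slot family `"poisson"`, `"hermite"`, `"neymanA"` or `"negbin"`.
#' @slot mu positive mean count per cell.
#' @slot delta dispersion index (>= 1).
#' @export
setClass("CountModel",
  representation(family = "character", mu = "numeric", delta = "numeric"))

setValidity("CountModel", function(object) {
  if (length(object@family) != 1L || !object@family %in% .families)
    return(sprintf("family must be one of: %s",
                   paste(.families, collapse = ", ")))
  if (length(object@mu) != 1L || !is.finite(object@mu) || object@mu <= 0)
    return("mu must be a single positive number")
  d <- object@delta
  if (length(d) != 1L || !is.finite(d)) return("delta must be a single number")
  if (object@family == "poisson" && d != 1)
    return("poisson requires delta = 1")
  if (d < 1) return("delta must be >= 1")
  if (object@family == "hermite" && d > 2)
    return("hermite requires delta <= 2 (Bin(2, delta-1) generalizing law)")
  TRUE
})

#' Calibration dataset
#'
#' Dose-wise frequency distributions of aberration counts: row `i` holds the
#' number of cells with 0, 1, 2, ... aberrations scored at dose `dose[i]`.
#'
#' @slot dose numeric vector of distinct nonnegative doses (Gy).
#' @slot counts integer matrix, one row per dose, column `k+1` = number of
#'   cells with `k` aberrations.
#' @export
setClass("CalibrationData",
  representation(dose = "numeric", counts = "matrix"))

setValidity("CalibrationData", function(object) {
  if (nrow(object@counts) != length(object@dose))
    return("counts must have one row per dose")
  if (any(!is.finite(object@dose)) || any(object@dose < 0))
    return("doses must be finite and nonnegative")
  if (anyDuplicated(object@dose)) return("doses must be distinct")
  cn <- object@counts
  if (any(!is.finite(cn)) || any(cn < 0) || any(cn != round(cn)))
    return("cell counts must be nonnegative integers")
  if (any(rowSums(cn) < 1)) return("every dose needs at least one cell")
  TRUE
})

#' Test (patient) sample
#'
#' The frequency distribution of aberration counts in the `m` cells scored
#' for the individual whose dose is to be estimated; `s` is the total number
#' of aberrations.
#'
#' @slot freq numeric vector, element `k+1` = number of cells with `k`
#'   aberrations.
#' @slot trueDose simulated ground-truth dose (Gy), `NA` for real samples.
#' @export
setClass("TestSample",
  representation(freq = "numeric", trueDose = "numeric"))

setValidity("TestSample", function(object) {
  f <- object@freq
  if (length(f) < 1L || any(!is.finite(f)) || any(f < 0) ||
      any(f != round(f)))
    return("freq must be nonnegative integer counts of cells")
  if (sum(f) < 1) return("at least one cell is required")
  if (length(object@trueDose) != 1L)
    return("trueDose must be a single number (NA if unknown)")
  TRUE
})

#' Fitted calibration
#'
#' The output of the calibration stage: the maximum-likelihood (or imported)
#' dose-response coefficients, the dispersion index for compound families,
#' and the covariance matrix of all free parameters, from which the
#' delta-method mean prior at any dose is derived.
#'
#' @slot family response family.
#' @slot curve fitted [DoseResponseCurve-class].
#' @slot delta fitted dispersion index (1 for Poisson).
#' @slot cov covariance matrix of the free parameters (coefficients, plus a
#'   trailing `delta` row/column for compound families).
#' @slot loglik maximized log-likelihood (`NA` for imported fits).
#' @slot bic Bayesian information criterion, `-2 loglik + p log(N)` with `N`
#'   the total number of scored cells (`NA` for imported fits).
#' @slot nCells total number of cells in the calibration data.
#' @slot doseRange dose range (Gy) covered by the calibration design; used
#'   to delimit root searches and default grids.
#' @slot boundary `TRUE` if some parameter sits on its constraint boundary
#'   (a zero coefficient or `delta` at 1), in which case the covariance is
#'   only indicative.
#' @export
setClass("FittedCalibration",
  representation(family = "character", curve = "DoseResponseCurve",
                 delta = "numeric", cov = "matrix", loglik = "numeric",
                 bic = "numeric", nCells = "numeric", doseRange = "numeric",
                 boundary = "logical"))

setValidity("FittedCalibration", function(object) {
  if (!object@family %in% .families) return("unknown family")
  p <- length(object@curve@beta) + (object@family != "poisson")
  if (!all(dim(object@cov) == c(p, p)))
    return("cov dimension must match the number of free parameters")
  if (max(abs(object@cov - t(object@cov))) > 1e-8 * (1 + max(abs(object@cov))))
    return("cov must be symmetric")
  ev <- eigen(object@cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1e-300))
    return("cov must be positive semi-definite")
  if (object@delta < 1) return("delta must be >= 1")
  if (length(object@doseRange) != 2L || diff(object@doseRange) <= 0)
    return("doseRange must be an increasing pair of doses")
  TRUE
})

#' Prior distribution for the dose
#'
#' @slot kind `"flat"` (improper uniform on `[0, Inf)`), `"uniform"` (proper
#'   on `[min, max]`) or `"gamma"` (parametrized by mean and sd).
#' @slot par numeric parameters: `c(min, max)` for uniform, `c(mean, sd)`
#'   for gamma, empty for flat.
#' @export
setClass("DosePrior", representation(kind = "character", par = "numeric"))

setValidity("DosePrior", function(object) {
  k <- object@kind
  if (!k %in% c("flat", "uniform", "gamma")) return("unknown prior kind")
  if (k == "uniform" &&
      (length(object@par) != 2L || object@par[1] < 0 ||
       object@par[2] <= object@par[1]))
    return("uniform prior needs 0 <= min < max")
  if (k == "gamma" && (length(object@par) != 2L || any(object@par <= 0)))
    return("gamma prior needs positive mean and sd")
  TRUE
})

#' Calibrative density of the absorbed dose
#'
#' The normalized posterior density of the dose given the test sample,
#' \eqn{f(x | y) \propto p(x) q_s(x)}, tabulated on a grid, together with
#' its summaries (mode, mean, sd, equal-tail credible interval).
#'
#' @slot dose increasing dose grid (Gy).
#' @slot density nonnegative density values, trapezoid-normalized to 1.
#' @slot prior the [DosePrior-class] used.
#' @slot method `"poisson"`, `"simplified"` or `"complete"`.
#' @slot meanPrior `"normal"` or `"gamma"`.
#' @slot summaries list with elements `mode`, `mean`, `sd`, `ci`, `level`.
#' @export
setClass("CalibrativeDensity",
  representation(dose = "numeric", density = "numeric", prior = "DosePrior",
                 method = "character", meanPrior = "character",
                 summaries = "list"))

setValidity("CalibrativeDensity", function(object) {
  if (length(object@dose) != length(object@density))
    return("dose and density lengths differ")
  if (is.unsorted(object@dose, strictly = TRUE))
    return("dose grid must be strictly increasing")
  if (any(object@density < 0)) return("density must be nonnegative")
  tot <- pracma::trapz(object@dose, object@density)
  if (abs(tot - 1) > 1e-6)
    return(sprintf("density must integrate to 1 (got %.8f)", tot))
  TRUE
})
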