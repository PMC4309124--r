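## Maximum-likelihood calibration fitting.

## log-likelihood of a calibration dataset under (curve, family, delta)
.calibLogLik <- function(data, family, curve, delta) {
  f <- curveMean(curve, data@dose)
  if (any(!is.finite(f)) || any(f < 0)) return(-Inf)
  cn <- data@counts
  K <- ncol(cn) - 1L
  tot <- 0
  for (i in seq_along(data@dose)) {
    w <- cn[i, ]
    obs <- w > 0
    if (!any(obs)) next
    if (f[i] < 1e-12) {
      if (any(obs[-1])) return(-Inf)  # positive counts at zero mean
      next
    }
    lp <- .countLogPmf(family, K, f[i], delta)
    if (any(!is.finite(lp[obs]))) return(-Inf)
    tot <- tot + sum(w[obs] * lp[obs])
  }
  tot
}

## moment-based starting values: weighted LS on the per-dose means for beta,
## cell-weighted mean of the per-dose dispersion coefficients for delta
.fitStart <- function(data, family, form, G) {
  x <- data@dose
  cn <- data@counts
  k <- seq_len(ncol(cn)) - 1
  n <- rowSums(cn)
  z <- as.numeric(cn %*% k)
  yb <- z / n
  X <- switch(form, linear = cbind(x), linquad0 = cbind(x, x^2),
              linquad = cbind(1, x, G * x^2))
  b <- tryCatch(stats::lm.wfit(X, yb, w = n)$coefficients,
                error = function(e) rep(NA_real_, ncol(X)))
  b[!is.finite(b)] <- 0
  b <- pmax(b, 1e-6 * max(mean(yb), 1e-3))
  delta0 <- 1
  if (family != "poisson") {
    s2 <- (as.numeric(cn %*% k^2) - n * yb^2) / pmax(n - 1, 1)
    d <- ifelse(yb > 0, s2 / yb, 1)
    delta0 <- max(1.001, sum(n * d) / sum(n))
    if (family == "hermite") delta0 <- min(delta0, 1.95)
  }
  list(beta = as.numeric(b), delta = delta0)
}

#' Fit a dose-response calibration curve by maximum likelihood
#'
#' Maximizes the per-cell likelihood
#' \eqn{L(D|\Theta) = \prod_{i,j} p(y_{ij} | f(x_i, \beta), \delta)}
#' over the nonnegative curve coefficients and, for compound families, the
#' common dispersion index \eqn{\delta}. The optimizer is a multi-start
#' box-constrained quasi-Newton search followed by Newton polishing on
#' finite-difference derivatives; the parameter covariance is the inverse
#' of the finite-difference observed information at the optimum.
#'
#' @param data a [CalibrationData-class].
#' @param family response family (see [CountModel()]).
#' @param form,G dose-response curve form and protraction factor (see
#'   [DoseResponseCurve()]).
#' @param hessianStep relative step of the finite-difference Hessian used
#'   for the covariance (central differences; coordinates at a constraint
#'   boundary fall back to one-sided differences).
#' @return a [FittedCalibration-class]. A boundary solution (a coefficient
#'   at 0 or \eqn{\hat\delta} at 1) is kept in the covariance and flagged
#'   with a warning.
#' @examples
#' cd <- exampleCalibration("dicentrics")
#' fit <- fitCalibration(dropDose(cd, 1.5), "poisson", "linquad0")
#' coef(fit)
#' @export
fitCalibration <- function(data,
                           family = c("poisson", "hermite", "neymanA",
                                      "negbin"),
                           form = c("linquad0", "linquad", "linear"),
                           G = 1, hessianStep = 1e-4) {
  family <- match.arg(family)
  form <- match.arg(form)
  p <- switch(form, linear = 1L, linquad0 = 2L, linquad = 3L)
  if (length(data@dose) < p)
    stop("need at least ", p, " doses for a ", p, "-coefficient curve")
  hasDelta <- family != "poisson"
  st <- .fitStart(data, family, form, G)

  mkCurve <- function(b) DoseResponseCurve(form, b, G)
  nll <- function(th) {
    b <- th[seq_len(p)]
    delta <- if (hasDelta) th[p + 1L] else 1
    -(.calibLogLik(data, family, mkCurve(pmax(b, 0)), delta))
  }

  lower <- c(rep(0, p), if (hasDelta) 1 + 1e-8)
  upper <- c(rep(Inf, p),
             if (hasDelta) (if (family == "hermite") 2 else Inf))
  starts <- list(c(st$beta, if (hasDelta) st$delta))
  if (hasDelta) {
    starts <- c(starts,
                list(c(st$beta, 1.01)),
                list(c(st$beta, min(if (family == "hermite") 1.9 else 3,
                                    1 + 2 * (st$delta - 1) + 0.2))))
  }
  starts <- c(starts, list(c(st$beta * 0.6, if (hasDelta) st$delta)),
              list(c(st$beta * 1.6, if (hasDelta) st$delta)))

  best <- NULL
  for (s0 in starts) {
    s0 <- pmin(pmax(s0, lower + 1e-9), ifelse(is.finite(upper),
                                              upper - 1e-9, s0))
    o <- tryCatch(
      optim(s0, nll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 1000, factr = 1e4,
                           parscale = pmax(abs(s0), 1e-4))),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best) || !is.finite(best$value))
    stop("calibration fit failed to converge from all starting points")

  ## Newton polish on interior coordinates
  th <- best$par
  for (it in 1:30) {
    free <- which(th - lower > 1e-7 &
                  (!is.finite(upper) | upper - th > 1e-7))
    if (!length(free)) break
    g <- .fdGrad(function(z) { t2 <- th; t2[free] <- z; nll(t2) }, th[free])
    H <- .fdHess(function(z) { t2 <- th; t2[free] <- z; nll(t2) }, th[free],
                 relStep = 1e-4)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    new <- th
    lam <- 1
    repeat {
      new[free] <- pmin(pmax(th[free] - lam * step,
                             lower[free] + 1e-10),
                        ifelse(is.finite(upper[free]),
                               upper[free] - 1e-12, Inf))
      if (nll(new) <= best$value + 1e-9 || lam < 1e-4) break
      lam <- lam / 2
    }
    if (nll(new) >= best$value - 1e-12) break
    best$value <- nll(new)
    th <- new
    if (max(abs(lam * step) / pmax(abs(th[free]), 1e-6)) < 1e-10) break
  }

  boundary <- any(th[seq_len(p)] < 1e-8) ||
    (hasDelta && (th[p + 1L] - 1 < 1e-6 ||
                  (family == "hermite" && 2 - th[p + 1L] < 1e-6)))
  if (boundary)
    warning("boundary solution (coefficient at 0 or delta at its limit); ",
            "covariance is only indicative")

  H <- .fdHess(nll, th, lower = lower, upper = upper, relStep = hessianStep)
  cov <- tryCatch(solve(H), error = function(e)
    stop("observed information is singular at the optimum"))
  cov <- (cov + t(cov)) / 2
  ## clip tiny negative eigenvalues from finite differencing
  ev <- eigen(cov, symmetric = TRUE)
  if (min(ev$values) < 0)
    cov <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
  nm <- c(names(mkCurve(th[seq_len(p)])@beta), if (hasDelta) "delta")
  dimnames(cov) <- list(nm, nm)

  loglik <- -best$value
  N <- sum(data@counts)
  new("FittedCalibration", family = family,
      curve = mkCurve(th[seq_len(p)]),
      delta = if (hasDelta) th[p + 1L] else 1,
      cov = cov, loglik = loglik,
      bic = -2 * loglik + length(th) * log(N),
      nCells = N, doseRange = c(0, max(data@dose)), boundary = boundary)
}

#' Compare the four response families by BIC
#'
#' Fits all four families with the same curve form and returns their BIC
#' values (`-2 loglik + p log N`, `N` = total scored cells); the smallest
#' value identifies the preferred response model. A family whose fit fails
#' gets `NA` rather than aborting the table.
#'
#' @inheritParams fitCalibration
#' @param families subset of families to compare.
#' @return named numeric vector of BIC values.
#' @export
bicTable <- function(data, form = c("linquad0", "linquad", "linear"), G = 1,
                     families = c("poisson", "hermite", "neymanA",
                                  "negbin")) {
  form <- match.arg(form)
  vapply(families, function(fam) {
    tryCatch(suppressWarnings(
      fitCalibration(data, fam, form, G)@bic),
      error = function(e) NA_real_)
  }, numeric(1))
}

#' Import an externally fitted calibration curve
#'
#' Builds a [FittedCalibration-class] from published fit results (the
#' situation where a laboratory provides only \eqn{\hat\beta} and its
#' uncertainty, not the calibration counts). The covariance may be given
#' directly via `cov`, or assembled from standard errors: `rho` is the
#' correlation of `beta1` and `beta2`, while an intercept `beta0` (commonly
#' re-estimated from a pre-exposure sample) is taken uncorrelated with the
#' curve coefficients.
#'
#' @param form,G curve form and protraction factor ([DoseResponseCurve()]).
#' @param beta coefficients, ordered `(beta0,) beta1, beta2`.
#' @param se standard errors of `beta` (same order); ignored when `cov` is
#'   given.
#' @param rho correlation between `beta1` and `beta2`.
#' @param cov full covariance matrix of the coefficients (and of `delta` as
#'   a trailing row for compound families).
#' @param family,delta response family and its dispersion index.
#' @param deltaVar variance of `delta` (appended to an se-built covariance).
#' @param doseRange dose range (Gy) over which the imported curve is valid.
#' @return a [FittedCalibration-class] with `NA` log-likelihood and BIC.
#' @examples
#' fit <- importFit("linquad", beta = c(10e-3, 13.6e-3, 3.7e-3),
#'                  se = c(4.450e-3, 5.5e-3, 1.6e-3), rho = -0.89, G = 0.1)
#' @export
importFit <- function(form = c("linquad0", "linquad", "linear"), beta,
                      se = NULL, rho = 0, cov = NULL, G = 1,
                      family = c("poisson", "hermite", "neymanA", "negbin"),
                      delta = 1, deltaVar = 0, doseRange = c(0, 5)) {
  form <- match.arg(form)
  family <- match.arg(family)
  curve <- DoseResponseCurve(form, beta, G)
  p <- length(curve@beta)
  hasDelta <- family != "poisson"
  if (is.null(cov)) {
    if (is.null(se) || length(se) != p || any(se <= 0))
      stop("give either 'cov' or ", p, " positive standard errors 'se'")
    if (abs(rho) > 1) stop("|rho| must be <= 1")
    R <- diag(p)
    i1 <- match("beta1", names(curve@beta))
    i2 <- match("beta2", names(curve@beta))
    if (!is.na(i1) && !is.na(i2)) R[i1, i2] <- R[i2, i1] <- rho
    cov <- diag(se, p) %*% R %*% diag(se, p)
    if (hasDelta) cov <- rbind(cbind(cov, 0), c(rep(0, p), deltaVar))
  } else {
    cov <- as.matrix(cov)
    q <- p + hasDelta
    if (!all(dim(cov) == q)) stop("cov must be ", q, "x", q)
  }
  nm <- c(names(curve@beta), if (hasDelta) "delta")
  dimnames(cov) <- list(nm, nm)
  if (min(eigen((cov + t(cov)) / 2, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-12 * max(abs(cov)))
    stop("the assembled covariance matrix is not positive semi-definite")
  new("FittedCalibration", family = family, curve = curve,
      delta = as.numeric(delta), cov = (cov + t(cov)) / 2,
      loglik = NA_real_, bic = NA_real_, nCells = NA_real_,
      doseRange = as.numeric(doseRange), boundary = FALSE)
}

## --- accessors -----------------------------------------------------------

#' @describeIn fitCalibration coefficient estimates (curve coefficients,
#'   plus `delta` for compound families).
#' @param object a `FittedCalibration`.
#' @export
setMethod("coef", "FittedCalibration", function(object) {
  c(object@curve@beta,
    if (object@family != "poisson") c(delta = object@delta))
})

#' @describeIn fitCalibration parameter covariance matrix.
#' @export
setMethod("vcov", "FittedCalibration", function(object) object@cov)

#' @describeIn fitCalibration maximized log-likelihood.
#' @export
setMethod("logLik", "FittedCalibration", function(object) object@loglik)

#' @describeIn fitCalibration Bayesian information criterion.
#' @export
setMethod("BIC", "FittedCalibration", function(object) object@bic)

#' @describeIn fitCalibration response family of the fit.
#' @export
setMethod("responseFamily", "FittedCalibration",
          function(object) object@family)

#' @describeIn fitCalibration fitted dispersion index.
#' @export
setMethod("dispersionIndex", "FittedCalibration",
          function(object) object@delta)

#' @describeIn fitCalibration the fitted [DoseResponseCurve-class].
#' @export
setMethod("doseResponse", "FittedCalibration", function(object) object@curve)

setMethod("show", "FittedCalibration", function(object) {
  cat(sprintf("FittedCalibration: %s response, %s curve%s\n", object@family,
              object@curve@form,
              if (is.na(object@loglik)) " (imported)" else ""))
  est <- coef(object)
  se <- sqrt(diag(object@cov))
  print(data.frame(estimate = signif(est, 5), se = signif(se, 4)))
  if (!is.na(object@bic))
    cat(sprintf("logLik %.3f, BIC %.3f (N = %d cells)\n", object@loglik,
                object@bic, as.integer(object@nCells)))
  if (object@boundary) cat("note: boundary solution\n")
  invisible(object)
})
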