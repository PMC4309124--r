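## Predictive probability q_s(x) of the test total s at candidate dose x.
##
## Poisson responses: mixing Pois(m mu) over the normal mean prior gives a
## Hermite law (Kemp & Kemp), over the gamma mean prior a negative binomial;
## q_s is a single pmf evaluation. Compound responses (dispersion fixed at
## its MLE) give compound Hermite / compound NB laws, evaluated by the
## recursion of the compound-Hermite proposition and by Panjer's recursion
## respectively.

## generalizing distribution of each compound family, as a pmf vector f_0..
.generalizingPmf <- function(family, delta, kmax) {
  switch(family,
    neymanA = dpois(0:kmax, delta - 1),
    negbin = {
      theta <- (delta - 1) / delta  # logarithmic, zero-truncated
      k <- seq_len(kmax)
      c(0, exp(k * log(theta) - log(k) - log(log(delta))))
    },
    hermite = dbinom(0:min(2, kmax), 2, delta - 1),
    stop("no generalizing law for family ", family))
}

## scale factor c such that the counting distribution is F(c f, 1 + c v/f)
.countingScale <- function(family, m, delta) {
  switch(family,
    neymanA = m / (delta - 1),
    negbin = m * log(delta) / (delta - 1),
    hermite = m / (2 * (delta - 1)))
}

#' Compound distribution probabilities by Panjer recursion
#'
#' Probabilities `q_0..q_kmax` of a compound distribution whose counting
#' law is negative binomial (`delta > 1`) or Poisson (`delta = 1`), with
#' mean `mu` and dispersion index `delta`, and whose generalizing law has
#' pmf `gen` (`gen[j+1]` = P(xi = j)). Uses the (a, b, 0)-class recursion
#' \eqn{q_i = \sum_j (a + b j/i) f_j q_{i-j}} with
#' \eqn{q_0 = pgf(f_0)}, run in linear space with rescaling.
#'
#' @param mu,delta mean and dispersion index of the counting law.
#' @param gen numeric pmf vector of the generalizing law (may be truncated;
#'   only the first `kmax + 1` entries are used).
#' @param kmax largest count needed.
#' @param log return log probabilities.
#' @return numeric vector of length `kmax + 1`.
#' @examples
#' # compounding with a point mass at 1 returns the counting law itself
#' panjerCompound(2, 1.5, c(0, 1), 5)
#' dnbinom(0:5, size = 4, prob = 1 / 1.5)
#' @export
panjerCompound <- function(mu, delta, gen, kmax, log = FALSE) {
  stopifnot(mu >= 0, delta >= 1, kmax >= 0)
  if (any(gen < 0) || sum(gen) > 1 + 1e-8)
    stop("gen must be a (possibly truncated) pmf")
  f0 <- gen[1]
  if (delta - 1 < 1e-10) {  # Poisson counting
    lp <- .panjerLogPmf(0, mu, mu * (f0 - 1), gen, kmax)
  } else {
    a <- (delta - 1) / delta
    b <- (mu - delta + 1) / delta
    r <- mu / (delta - 1)
    p <- 1 / delta
    logq0 <- r * (base::log(p) - base::log(1 - (1 - p) * f0))
    lp <- .panjerLogPmf(a, b, logq0, gen, kmax)
  }
  if (log) lp else exp(lp)
}

#' Compound distribution probabilities for a Hermite counting law
#'
#' Probabilities `q_0..q_kmax` of a compound Hermite distribution
#' (counting law Hermite with mean `mu` and dispersion index
#' `delta` in (1, 2]), computed by the two-term recursion on the
#' generalizing pmf `gen` and its self-convolution
#' \eqn{r_j = \sum_i f_i f_{j-i}}:
#' \deqn{q_n = \frac{\mu}{n} \sum_{i=0}^{n-1} (n-i) q_i
#'   \left[(2-\delta) f_{n-i} + \frac{\delta-1}{2} r_{n-i}\right]}
#' seeded at the Hermite pgf evaluated at \eqn{f_0}.
#'
#' @inheritParams panjerCompound
#' @examples
#' # point mass at 1 recovers the Hermite pmf itself
#' hermiteCompound(1, 1.5, c(0, 1), 4)
#' countPmf(CountModel("hermite", 1, 1.5), 0:4)
#' @export
hermiteCompound <- function(mu, delta, gen, kmax, log = FALSE) {
  stopifnot(mu >= 0, kmax >= 0)
  if (delta < 1 || delta > 2)
    stop("the Hermite counting law needs delta in [1, 2]")
  if (any(gen < 0) || sum(gen) > 1 + 1e-8)
    stop("gen must be a (possibly truncated) pmf")
  lp <- .hermiteCompoundLogPmf(mu, delta, gen, kmax)
  if (log) lp else exp(lp)
}

## q_s(x) on the log scale, one value per dose in x
.qsLog <- function(fit, s, m, x, meanPrior = c("normal", "gamma")) {
  meanPrior <- match.arg(meanPrior)
  mv <- meanVariance(fit, x)
  compound <- fit@family != "poisson"
  delta <- fit@delta
  vapply(seq_along(x), function(i) {
    f <- mv$mean[i]
    v <- mv$var[i]
    if (f < 1e-14) return(if (s == 0) 0 else -Inf)
    if (!compound) {
      if (v <= 0 || m * v / f < 1e-12)   # no parameter uncertainty
        return(dpois(s, m * f, log = TRUE))
      if (meanPrior == "normal") {
        deltaH <- 1 + m * v / f
        if (deltaH > 2 + 1e-5)
          stop("normal mean prior inadmissible at x = ", signif(x[i], 4),
               " Gy (beyond the validity bound); use the gamma mean prior")
        .hermiteCompoundLogPmf(m * f, min(deltaH, 2), c(0, 1), s)[s + 1]
      } else {
        dnbinom(s, size = f^2 / v, mu = m * f, log = TRUE)
      }
    } else {
      cc <- .countingScale(fit@family, m, delta)
      if (v <= 0 || cc * v / f < 1e-12)  # degenerate prior: summed family law
        return(.countLogPmf(fit@family, s, m * f, delta)[s + 1])
      muF <- cc * f
      deltaF <- 1 + cc * v / f
      gen <- .generalizingPmf(fit@family, delta, s)
      if (meanPrior == "normal") {
        if (deltaF > 2 + 1e-5)
          stop("normal mean prior inadmissible at x = ", signif(x[i], 4),
               " Gy for the ", fit@family,
               " family; use the gamma mean prior")
        .hermiteCompoundLogPmf(muF, min(deltaF, 2), gen, s)[s + 1]
      } else {
        a <- (deltaF - 1) / deltaF
        b <- (muF - deltaF + 1) / deltaF
        logq0 <- muF / (deltaF - 1) *
          (base::log(1 / deltaF) - base::log(1 - (1 - 1 / deltaF) * gen[1]))
        .panjerLogPmf(a, b, logq0, gen, s)[s + 1]
      }
    }
  }, numeric(1))
}

#' Predictive probability of the test total at candidate doses
#'
#' \eqn{q_s(x)}: the probability that the summed test sample takes the
#' value `s`, mixing the response law over the mean prior at dose `x`.
#' For a Poisson calibration this is a Hermite (normal mean prior) or
#' negative binomial (gamma mean prior) pmf with mean \eqn{m f(x)} and
#' variance \eqn{m f(x) + m^2 v(x)}; for a compound calibration (with
#' \eqn{\delta} fixed at its estimate) it is the corresponding compound
#' Hermite or compound negative binomial pmf.
#'
#' @param fit a [FittedCalibration-class].
#' @param s total aberrations in the test sample.
#' @param m cells scored in the test sample.
#' @param x numeric vector of doses (Gy).
#' @param meanPrior `"normal"` or `"gamma"`. The normal variant errors at
#'   doses beyond [normalValidityBound()].
#' @param log return log probabilities.
#' @return numeric vector, one probability per dose.
#' @export
predictiveProb <- function(fit, s, m, x,
                           meanPrior = c("normal", "gamma"), log = FALSE) {
  stopifnot(s >= 0, s == round(s), m >= 1)
  lp <- .qsLog(fit, s, m, x, match.arg(meanPrior))
  if (log) lp else exp(lp)
}

#' Complete-model predictive value by two-dimensional integration
#'
#' For compound families, the complete model does not plug in
#' \eqn{\hat\delta} but integrates the full per-cell test likelihood
#' against the bivariate normal prior of \eqn{(\mu, \delta)} at dose `x`:
#' \deqn{q(x) = \int\!\!\int L(\tilde y | \mu, \delta)
#'   \phi(\mu, \delta | x)\, d\mu\, d\delta,}
#' evaluated by tensor Gauss-Legendre quadrature over a box of
#' `halfwidth` prior standard deviations per axis (`delta` truncated to its
#' family range, `mu` to positives), in log space.
#'
#' @param fit a compound-family [FittedCalibration-class] whose covariance
#'   includes the `delta` row.
#' @param test a [TestSample-class].
#' @param x numeric vector of doses (Gy).
#' @param nodes Gauss-Legendre nodes per axis.
#' @param halfwidth integration box half-width in prior standard deviations.
#' @param log return the log value.
#' @return numeric vector, one (unnormalized likelihood) value per dose.
#' @export
predictiveProbComplete <- function(fit, test, x, nodes = 48, halfwidth = 6,
                                   log = FALSE) {
  bp <- bivariatePrior(fit, x)
  freq <- test@freq
  kk <- which(freq > 0) - 1L
  wk <- freq[freq > 0]
  gl <- pracma::gaussLegendre(nodes, -1, 1)
  deltaMax <- if (fit@family == "hermite") 2 - 1e-9 else Inf
  fam <- fit@family
  out <- vapply(seq_along(x), function(i) {
    f <- bp$mean[i, 1]
    Sig <- bp$cov[, , i]
    sdm <- sqrt(Sig[1, 1]); sdd <- sqrt(Sig[2, 2])
    loM <- max(1e-10, f - halfwidth * sdm); hiM <- f + halfwidth * sdm
    loD <- max(1 + 1e-9, fit@delta - halfwidth * sdd)
    hiD <- min(deltaMax, fit@delta + halfwidth * sdd)
    if (hiM <= loM || hiD <= loD) return(-Inf)
    muN <- (loM + hiM) / 2 + (hiM - loM) / 2 * gl$x
    wM <- (hiM - loM) / 2 * gl$w
    dlN <- (loD + hiD) / 2 + (hiD - loD) / 2 * gl$x
    wD <- (hiD - loD) / 2 * gl$w
    Si <- solve(Sig)
    ldet <- as.numeric(determinant(Sig)$modulus)
    ## log test likelihood on the (mu, delta) node grid
    M <- matrix(0, nodes, nodes)
    if (fam == "negbin") {
      for (j in seq_along(kk))
        M <- M + wk[j] * outer(muN, dlN, function(mm, dd)
          dnbinom(kk[j], size = mm / (dd - 1), prob = 1 / dd, log = TRUE))
    } else {
      K <- max(kk)
      for (a2 in seq_len(nodes)) for (b2 in seq_len(nodes)) {
        lp <- .countLogPmf(fam, K, muN[a2], dlN[b2])
        M[a2, b2] <- sum(wk * lp[kk + 1])
      }
    }
    dm <- muN - f; dd2 <- dlN - fit@delta
    M <- M - 0.5 * (outer(Si[1, 1] * dm^2, Si[2, 2] * dd2^2, "+") +
                    2 * Si[1, 2] * outer(dm, dd2)) -
      0.5 * ldet - base::log(2 * pi)
    mx <- max(M)
    if (!is.finite(mx)) return(-Inf)
    mx + base::log(sum(exp(M - mx) * outer(wM, wD)))
  }, numeric(1))
  if (log) out else exp(out)
}
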