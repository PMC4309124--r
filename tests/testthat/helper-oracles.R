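## Independent brute-force oracles used to validate the recursions.

## truncated convolution of two pmf vectors (index k+1 = P(k))
convTrunc <- function(a, b, kmax) {
  out <- numeric(kmax + 1)
  for (i in seq_along(a) - 1) {
    if (a[i + 1] == 0) next
    jmax <- min(kmax - i, length(b) - 1)
    if (jmax >= 0)
      out[i + (0:jmax) + 1] <- out[i + (0:jmax) + 1] +
        a[i + 1] * b[(0:jmax) + 1]
  }
  out
}

## distribution of sum_{i=1}^N xi by direct enumeration over N:
## countProbs[n+1] = P(N = n) (truncated), genProbs = pmf of xi
bruteCompound <- function(countProbs, genProbs, kmax) {
  out <- countProbs[1] * c(1, numeric(kmax))
  conv <- c(1, numeric(kmax))
  for (n in seq_along(countProbs)[-1] - 1) {
    conv <- convTrunc(conv, genProbs, kmax)
    out <- out + countProbs[n + 1] * conv
  }
  out
}

## Hermite(mu, delta) pmf by its definition Y = X1 + 2 X2,
## X1 ~ Pois(mu(2-delta)), X2 ~ Pois(mu(delta-1)/2)
bruteHermite <- function(mu, delta, kmax) {
  a <- mu * (2 - delta)
  b <- mu * (delta - 1) / 2
  vapply(0:kmax, function(k) {
    j <- 0:(k %/% 2)
    sum(dpois(k - 2 * j, a) * dpois(j, b))
  }, numeric(1))
}

## Neyman A(mu, delta) pmf by enumeration over the Poisson number of
## particles: sum_n P(N = n) Pois(k; n(delta-1))
bruteNeymanA <- function(mu, delta, kmax, nmax = 400) {
  lam <- mu / (delta - 1)
  phi <- delta - 1
  n <- 0:nmax
  pn <- dpois(n, lam)
  vapply(0:kmax, function(k) sum(pn * dpois(k, n * phi)), numeric(1))
}

## q_s(x) by direct numerical integration of the mixing integral,
## p(s | m mu, delta) against the mean prior.  The normal variant uses the
## formal full-line integrand for the Poisson response; for compound
## responses the prior must be tight enough (f >> sd) that truncating at
## mu > 0 is immaterial.
quadQs <- function(s, m, f, v, family = "poisson", delta = 1,
                   kind = c("normal", "gamma")) {
  kind <- match.arg(kind)
  pmfAt <- function(mu) {
    if (family == "poisson") {
      exp(-m * mu) * (m * mu)^s / factorial(s)  # valid for mu < 0 too
    } else {
      vapply(mu, function(mm) {
        if (mm <= 0) return(0)
        countPmf(CountModel(family, m * mm, delta), s)
      }, numeric(1))
    }
  }
  if (kind == "normal") {
    lo <- if (family == "poisson") f - 12 * sqrt(v) else
      max(1e-12, f - 12 * sqrt(v))
    stats::integrate(function(mu) pmfAt(mu) * dnorm(mu, f, sqrt(v)),
                     lo, f + 12 * sqrt(v), rel.tol = 1e-10,
                     abs.tol = 0)$value
  } else {
    sh <- f^2 / v
    stats::integrate(function(mu) pmfAt(mu) *
                       dgamma(mu, shape = sh, rate = sh / f),
                     0, f + 14 * sqrt(v), rel.tol = 1e-10, abs.tol = 0)$value
  }
}
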