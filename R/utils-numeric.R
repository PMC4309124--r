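## Numerical helpers: finite-difference derivatives honouring box bounds.

## central-difference gradient
.fdGrad <- function(fn, x, relStep = 1e-6) {
  h <- relStep * pmax(abs(x), 1e-4)
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h[j]
    (fn(x + e) - fn(x - e)) / (2 * h[j])
  }, numeric(1))
}

## Hessian by differences; coordinates too close to a bound use one-sided
## steps (signed step s_j chosen to stay inside [lower, upper]).
.fdHess <- function(fn, x, lower = rep(-Inf, length(x)),
                    upper = rep(Inf, length(x)), relStep = 1e-4) {
  p <- length(x)
  h <- relStep * pmax(abs(x), 1e-2)
  central <- (x - 2 * h >= lower) & (x + 2 * h <= upper)
  sgn <- ifelse(x + 2 * h <= upper, 1, -1)
  H <- matrix(0, p, p)
  f0 <- fn(x)
  for (j in seq_len(p)) {
    ej <- numeric(p); ej[j] <- h[j]
    H[j, j] <- if (central[j]) {
      (fn(x + ej) - 2 * f0 + fn(x - ej)) / h[j]^2
    } else {
      (f0 - 2 * fn(x + sgn[j] * ej) + fn(x + 2 * sgn[j] * ej)) / h[j]^2
    }
    if (j > 1) for (k in seq_len(j - 1)) {
      ek <- numeric(p); ek[k] <- h[k]
      if (central[j] && central[k]) {
        H[j, k] <- (fn(x + ej + ek) - fn(x + ej - ek) -
                    fn(x - ej + ek) + fn(x - ej - ek)) / (4 * h[j] * h[k])
      } else {
        sj <- sgn[j] * h[j]; sk <- sgn[k] * h[k]
        ejk <- numeric(p); ejk[j] <- sj; ejk[k] <- sk
        ejo <- numeric(p); ejo[j] <- sj
        eko <- numeric(p); eko[k] <- sk
        H[j, k] <- (fn(x + ejk) - fn(x + ejo) - fn(x + eko) + f0) / (sj * sk)
      }
      H[k, j] <- H[j, k]
    }
  }
  (H + t(H)) / 2
}

## trapezoid cumulative integral (same grid convention as pracma::trapz)
.cumtrapz <- function(x, y) {
  cumsum(c(0, diff(x) * (head(y, -1) + tail(y, -1)) / 2))
}
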