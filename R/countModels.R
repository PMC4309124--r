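#' Construct a count response model
#'
#' @param family `"poisson"`, `"hermite"`, `"neymanA"` or `"negbin"`.
#' @param mu population mean count per cell (> 0).
#' @param delta dispersion index, the variance-to-mean ratio (>= 1; must be
#'   1 for Poisson and at most 2 for Hermite). `delta = 1` dispatches every
#'   family to the Poisson law.
#' @return a [CountModel-class] object.
#' @examples
#' hm <- CountModel("hermite", mu = 1, delta = 1.5)
#' countPmf(hm, 0:5)
#' @export
CountModel <- function(family = c("poisson", "hermite", "neymanA", "negbin"),
                       mu, delta = 1) {
  family <- match.arg(family)
  if (delta == 1 && family != "poisson") family <- "poisson"
  new("CountModel", family = family, mu = as.numeric(mu),
      delta = as.numeric(delta))
}

## log pmf at k = 0..kmax for the (mu, delta) parametrization.
## delta == 1 (or numerically so) is dispatched to Poisson; mu ~ 0 returns a
## point mass at zero.
.countLogPmf <- function(family, kmax, mu, delta) {
  k <- 0:kmax
  if (mu < 1e-12) return(ifelse(k == 0, 0, -Inf))
  if (family == "poisson" || delta <= 1 + 1e-10)
    return(dpois(k, mu, log = TRUE))
  switch(family,
    negbin = dnbinom(k, size = mu / (delta - 1), prob = 1 / delta,
                     log = TRUE),
    hermite = .hermiteCompoundLogPmf(mu, delta, c(0, 1), kmax),
    neymanA = {
      lam <- mu / (delta - 1)
      phi <- delta - 1
      gen <- dpois(k, phi)
      .panjerLogPmf(0, lam, lam * (gen[1] - 1), gen, kmax)
    },
    stop("unknown family: ", family))
}

#' @describeIn CountModel probability mass function \eqn{P(Y = k)}.
#' @param object a `CountModel`.
#' @param k vector of nonnegative integer counts.
#' @param log return log probabilities.
#' @export
setMethod("countPmf", "CountModel", function(object, k, log = FALSE) {
  if (any(k < 0) || any(k != round(k)))
    stop("k must contain nonnegative integers")
  lp <- .countLogPmf(object@family, max(k), object@mu, object@delta)[k + 1]
  if (log) lp else exp(lp)
})

#' @describeIn CountModel log-likelihood of a frequency vector of counts
#'   (element `k+1` = number of cells with `k` aberrations),
#'   \eqn{\sum_k n_k \log P(Y = k)}. Cells observed at counts of zero
#'   probability give an error rather than a silent `-Inf`.
#' @param freq frequency vector of counts per cell.
#' @export
setMethod("countLogLik", "CountModel", function(object, freq) {
  if (any(freq < 0) || any(freq != round(freq)) || sum(freq) < 1)
    stop("freq must be nonnegative integer cell counts, at least one cell")
  lp <- .countLogPmf(object@family, length(freq) - 1L, object@mu,
                     object@delta)
  obs <- freq > 0
  if (any(!is.finite(lp[obs])))
    stop("observed count with zero probability under the model")
  sum(freq[obs] * lp[obs])
})

#' @describeIn CountModel draw `n` cells from the model via its compound
#'   (Poisson-stopped-sum) representation and return the frequency vector
#'   of counts. Uses the current RNG state; call `set.seed()` for
#'   reproducibility.
#' @param n number of cells to draw.
#' @export
setMethod("countSample", "CountModel", function(object, n) {
  if (n < 1) stop("n must be >= 1")
  y <- .sampleCounts(object@family, n, object@mu, object@delta)
  tabulate(y + 1L, nbins = max(y) + 1L)
})

.sampleCounts <- function(family, n, mu, delta) {
  if (mu <= 0) return(integer(n))
  if (family == "poisson" || delta <= 1 + 1e-12) return(rpois(n, mu))
  switch(family,
    hermite = rpois(n, mu * (2 - delta)) +
      2L * rpois(n, mu * (delta - 1) / 2),
    neymanA = {
      N <- rpois(n, mu / (delta - 1))
      rpois(n, (delta - 1) * N)  # sum of N iid Poisson(delta-1)
    },
    negbin = rnbinom(n, size = mu / (delta - 1), prob = 1 / delta))
}

setMethod("show", "CountModel", function(object) {
  cat(sprintf("CountModel: %s (mu = %g, delta = %g)\n", object@family,
              object@mu, object@delta))
  invisible(object)
})
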