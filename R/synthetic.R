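## Synthetic calibration experiments and patient samples with known truth.

## deterministic per-stream seeds derived from one top-level seed, so that
## per-dose streams are reproducible independently of vector lengths
.streamSeeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a calibration experiment
#'
#' Draws, for every design dose, the requested number of cells from the
#' response family at mean \eqn{f(x, \beta)} via its compound
#' representation, and returns the dose-wise frequency table. One
#' top-level seed drives deterministic per-dose streams, so the output is
#' reproducible and individual doses can be regenerated independently.
#'
#' @param doses numeric vector of design doses (Gy).
#' @param cells number of cells per dose (recycled).
#' @param curve the true [DoseResponseCurve-class].
#' @param family response family.
#' @param delta true dispersion index (1 for Poisson).
#' @param seed integer seed.
#' @return a [CalibrationData-class].
#' @examples
#' cv <- DoseResponseCurve("linquad0", c(3.1e-3, 2.5e-2))
#' simulateCalibration(c(0.5, 1, 2), 500, cv, seed = 1)
#' @export
simulateCalibration <- function(doses, cells, curve,
                                family = c("poisson", "hermite", "neymanA",
                                           "negbin"),
                                delta = 1, seed = 1) {
  family <- match.arg(family)
  cells <- rep_len(cells, length(doses))
  if (any(cells < 1)) stop("every dose needs at least one cell")
  mu <- curveMean(curve, doses)
  seeds <- .streamSeeds(seed, length(doses))
  rows <- lapply(seq_along(doses), function(i) {
    set.seed(seeds[i])
    y <- .sampleCounts(family, cells[i], mu[i], delta)
    tabulate(y + 1L, nbins = max(y, 0L) + 1L)
  })
  CalibrationData(doses, rows)
}

#' Simulate a patient (test) sample
#'
#' Draws `m` cells at mean \eqn{f(x_0, \hat\beta)} under the fitted family
#' and dispersion, recording the ground-truth dose.
#'
#' @param fit a [FittedCalibration-class].
#' @param dose true dose \eqn{x_0} (Gy).
#' @param m number of cells to score.
#' @param seed integer seed.
#' @return a [TestSample-class] with `trueDose` set.
#' @export
simulatePatient <- function(fit, dose, m, seed = 1) {
  if (m < 1) stop("m must be >= 1")
  if (dose < 0) stop("dose must be nonnegative")
  mu <- curveMean(fit@curve, dose)
  set.seed(seed)
  y <- .sampleCounts(fit@family, m, mu, fit@delta)
  TestSample(tabulate(y + 1L, nbins = max(y, 0L) + 1L), trueDose = dose)
}
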