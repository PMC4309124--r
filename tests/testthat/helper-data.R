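## Published reference values used across tests (the two worked examples).

## dispersion statistics printed alongside the bundled dicentric table
dicStats <- data.frame(
  dose = c(0.25, 0.75, 1.00, 1.50, 2.50, 3.00),
  ybar = c(0.004, 0.018, 0.025, 0.056, 0.105, 0.295),
  d = c(0.997, 1.026, 1.044, 1.003, 1.038, 1.012),
  u = c(-0.113, 0.952, 1.503, 0.092, 0.985, 0.334))

## and alongside the bundled micronucleus table
mnStats <- data.frame(
  dose = c(0, 0.10, 0.25, 0.50, 0.75, 1.00, 1.50, 2.00, 2.50, 3.00, 4.00),
  ybar = c(0.024, 0.050, 0.090, 0.119, 0.149, 0.189, 0.243, 0.383, 0.501,
           0.722, 1.013),
  d = c(1.156, 1.150, 1.306, 1.449, 1.257, 1.240, 1.270, 1.209, 1.201,
        1.206, 1.172),
  u = c(7.839, 7.526, 15.306, 22.484, 12.876, 12.009, 13.495, 10.471,
        10.077, 10.307, 8.628))

## published Poisson fit of the dicentric curve (1.5 Gy row held out)
dicBeta <- c(beta1 = 3.126e-3, beta2 = 2.537e-2)
dicCov <- matrix(c(7.205, -3.438, -3.438, 2.718), 2) * 1e-6

## published NB fit of the micronucleus curve (0.1 Gy row held out)
mnBeta <- c(beta0 = 3.639e-2, beta1 = 1.156e-1, beta2 = 3.241e-2)
mnDelta <- 1.231
mnCov <- matrix(c(
   73.749, -115.908,   29.210,   13.976,
 -115.908,  373.338, -110.398,   36.919,
   29.210, -110.398,   38.102,   -3.625,
   13.976,   36.919,   -3.625, 1133.825), 4, byrow = TRUE) * 1e-7

## imported fits built from the published parameters
importedDicFit <- function() {
  importFit("linquad0", beta = dicBeta, cov = dicCov, doseRange = c(0, 3))
}
importedMnFit <- function() {
  importFit("linquad", beta = mnBeta, cov = mnCov, family = "negbin",
            delta = mnDelta, doseRange = c(0, 4))
}

## cached maximum-likelihood fits of the bundled datasets (computed once
## per test run)
dicFitML <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- fitCalibration(dropDose(exampleCalibration("dicentrics"), 1.5),
                             "poisson", "linquad0")
    val
  }
})
mnFitML <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- fitCalibration(dropDose(exampleCalibration("micronuclei"), 0.1),
                             "negbin", "linquad")
    val
  }
})
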