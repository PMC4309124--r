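test_that("single-dose linear Poisson fit equals the closed-form MLE", {
  cd <- CalibrationData(2, list(c(80, 18, 2)))  # ybar = 22/100 at 2 Gy
  fit <- fitCalibration(cd, "poisson", "linear")
  expect_equal(unname(coef(fit)["beta1"]), 0.22 / 2, tolerance = 1e-6)
  # observed information for f = beta x: I = z x^2 / f^2 = z / beta^2
  expect_equal(unname(vcov(fit)[1, 1]), 0.11^2 / 22, tolerance = 1e-4)
})

test_that("Poisson fit of the dicentric data reproduces the published
           coefficients and BIC", {
  fit <- dicFitML()
  b <- coef(fit)
  expect_lt(abs(b[["beta1"]] - dicBeta[["beta1"]]), 1e-6)
  expect_lt(abs(b[["beta2"]] - dicBeta[["beta2"]]), 1e-5)
  expect_equal(BIC(fit), 4079.639, tolerance = 1e-5)
  expect_equal(fit@nCells, 9840)
})

test_that("finite-difference observed information matches the analytic
           Poisson information", {
  fit <- dicFitML()
  cd <- dropDose(exampleCalibration("dicentrics"), 1.5)
  x <- doses(cd)
  cn <- cellCounts(cd)
  z <- as.numeric(cn %*% (seq_len(ncol(cn)) - 1))
  f <- curveMean(doseResponse(fit), x)
  g <- cbind(x, x^2)
  Ian <- t(g) %*% ((z / f^2) * g)  # analytic observed information
  expect_equal(unname(vcov(fit)), unname(solve(Ian)), tolerance = 1e-4)
})

test_that("equal log-likelihoods and parameter counts give equal BIC; the
           Poisson model is BIC-preferred for the equidispersed data", {
  cd <- dropDose(exampleCalibration("dicentrics"), 1.5)
  tb <- suppressWarnings(bicTable(cd, "linquad0"))
  expect_equal(unname(which.min(tb)), 1L)  # poisson wins
  # compound BICs exceed Poisson by at most the one-parameter penalty
  expect_true(all(tb[-1] <= tb[1] + log(9840) + 1e-6))
  expect_true(all(tb[-1] >= tb[1] - 1e-6))
})

test_that("importFit assembles the covariance from SEs and rho, keeps the
           intercept uncorrelated, and validates PSD", {
  se <- c(4.450e-3, 5.5e-3, 1.6e-3)
  rho <- -0.89
  fit <- importFit("linquad", beta = c(10e-3, 13.6e-3, 3.7e-3), se = se,
                   rho = rho, G = 0.1)
  S <- vcov(fit)
  expect_equal(diag(S), se^2, ignore_attr = TRUE)
  expect_equal(S["beta1", "beta2"], rho * se[2] * se[3])
  expect_identical(S["beta0", "beta1"], 0)
  expect_identical(S["beta0", "beta2"], 0)
  # rho = 0 with equal SEs -> diagonal covariance
  d0 <- importFit("linquad0", beta = c(1e-3, 1e-3), se = c(2e-3, 2e-3))
  expect_equal(vcov(d0), diag(4e-6, 2), ignore_attr = TRUE)
  expect_error(importFit("linquad0", beta = c(1e-3, 1e-3),
                         se = c(2e-3, 2e-3), rho = 1.2), "rho")
  badCov <- matrix(c(1, 2, 2, 1), 2)  # indefinite
  expect_error(importFit("linquad0", beta = c(1e-3, 1e-3), cov = badCov),
               "positive semi-definite")
  # round trip: importing a fitted covariance reproduces v(x) identically
  ml <- dicFitML()
  imp <- importFit("linquad0", beta = coef(ml), cov = vcov(ml))
  x <- c(0.5, 1.5, 3)
  expect_identical(meanVariance(imp, x)$var, meanVariance(ml, x)$var)
})

test_that("fitting simulated calibration data recovers the truth within
           three standard errors", {
  cv <- DoseResponseCurve("linquad0", c(3.1e-3, 2.5e-2))
  ok <- 0
  reps <- 40
  for (r in seq_len(reps)) {
    cd <- simulateCalibration(c(0.25, 0.75, 1, 2.5, 3), 600, cv,
                              family = "poisson", seed = 100 + r)
    ft <- suppressWarnings(fitCalibration(cd, "poisson", "linquad0"))
    se <- sqrt(diag(vcov(ft)))
    ok <- ok + all(abs(coef(ft) - cv@beta) < 3 * se)
  }
  expect_gte(ok, 36)  # joint 3-SE coverage is ~0.99 per replicate
})

test_that("the parameter covariance shrinks like 1/cells", {
  cv <- DoseResponseCurve("linquad0", c(3.1e-3, 2.5e-2))
  v <- vapply(c(400, 1600), function(n) {
    cd <- simulateCalibration(c(0.5, 1, 2, 3), n, cv, family = "poisson",
                              seed = 7)
    suppressWarnings(vcov(fitCalibration(cd, "poisson", "linquad0"))[2, 2])
  }, numeric(1))
  expect_gt(v[1] / v[2], 2.5)
  expect_lt(v[1] / v[2], 6.5)
})

test_that("compound-family fitting recovers an overdispersed truth", {
  cv <- DoseResponseCurve("linquad", c(3.6e-2, 1.16e-1, 3.2e-2))
  cd <- simulateCalibration(c(0, 0.5, 1, 2, 3, 4), 1500, cv,
                            family = "negbin", delta = 1.23, seed = 11)
  ft <- fitCalibration(cd, "negbin", "linquad")
  se <- sqrt(diag(vcov(ft)))
  expect_true(all(abs(coef(ft) - c(cv@beta, delta = 1.23)) < 3.5 * se))
})
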