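test_that("Poisson-model predictive equals direct quadrature of the mixing
           integral", {
  fit <- importedDicFit()
  m <- 40
  for (s in c(0, 3, 12)) {
    for (x in c(0.6, 1.2, 2.0)) {
      mv <- meanVariance(fit, x)
      qN <- predictiveProb(fit, s, m, x, "normal")
      expect_equal(qN, quadQs(s, m, mv$mean, mv$var, kind = "normal"),
                   tolerance = 1e-6)
      qG <- predictiveProb(fit, s, m, x, "gamma")
      expect_equal(qG, quadQs(s, m, mv$mean, mv$var, kind = "gamma"),
                   tolerance = 1e-6)
    }
  }
})

test_that("simplified compound predictive equals direct quadrature of the
           compound mixing integral", {
  fit <- importedMnFit()
  m <- 40
  for (s in c(2, 8)) {
    for (x in c(0.5, 1.5)) {
      mv <- meanVariance(fit, x)
      qG <- predictiveProb(fit, s, m, x, "gamma")
      expect_equal(qG, quadQs(s, m, mv$mean, mv$var, family = "negbin",
                              delta = mnDelta, kind = "gamma"),
                   tolerance = 1e-6)
      qN <- predictiveProb(fit, s, m, x, "normal")
      # the prior here is tight (f >> sd), so truncating the formal
      # integral at 0 is immaterial
      expect_equal(qN, quadQs(s, m, mv$mean, mv$var, family = "negbin",
                              delta = mnDelta, kind = "normal"),
                   tolerance = 1e-6)
    }
  }
})

test_that("Panjer recursion: compounding identities", {
  # point mass at 1 reproduces the counting law
  expect_equal(panjerCompound(3, 1.6, c(0, 1), 25),
               dnbinom(0:25, size = 3 / 0.6, prob = 1 / 1.6),
               tolerance = 1e-12)
  # generalizing law degenerate at 0: all mass stays at zero
  expect_equal(panjerCompound(3, 1.6, c(1), 5), c(1, rep(0, 5)))
  # Poisson counting + logarithmic generalizing = negative binomial
  mu <- 2; delta <- 1.8
  lamC <- mu * log(delta) / (delta - 1)
  theta <- (delta - 1) / delta
  gen <- c(0, theta^(1:30) / ((1:30) * log(delta)))
  expect_equal(panjerCompound(lamC, 1, gen, 30),
               dnbinom(0:30, size = mu / (delta - 1), prob = 1 / delta),
               tolerance = 1e-10)
  # NB counting + logarithmic generalizing vs brute-force enumeration
  nProbs <- dnbinom(0:400, size = 5, prob = 0.55)
  expect_equal(panjerCompound(5 * 0.45 / 0.55, 1 / 0.55, gen, 25),
               bruteCompound(nProbs, gen[1:26], 25), tolerance = 1e-10)
  expect_error(panjerCompound(2, 1.5, c(0.5, 0.9), 5), "pmf")
})

test_that("compound-Hermite recursion matches identities and enumeration", {
  # point mass at 1 reproduces the Hermite law itself
  expect_equal(hermiteCompound(1.5, 1.4, c(0, 1), 20),
               countPmf(CountModel("hermite", 1.5, 1.4), 0:20),
               tolerance = 1e-12)
  # binomial generalizing law vs brute-force enumeration over the
  # Hermite counting variable
  nProbs <- countPmf(CountModel("hermite", 2, 1.6), 0:150)
  gen <- dbinom(0:2, 2, 0.35)
  expect_equal(hermiteCompound(2, 1.6, gen, 30),
               bruteCompound(nProbs, gen, 30), tolerance = 1e-10)
  # delta -> 1 approaches the Poisson-counting compound
  genL <- c(0.2, 0.5, 0.3)
  nearOne <- hermiteCompound(2, 1 + 1e-8, genL, 20)
  poisC <- panjerCompound(2, 1, genL, 20)
  expect_equal(nearOne, poisC, tolerance = 1e-6)
  expect_error(hermiteCompound(2, 2.4, genL, 5), "delta")
})

test_that("closed-form linear-response density cross-validates the grid
           pipeline", {
  ## calibration: two doses of Poisson cells under f = beta x
  cv <- DoseResponseCurve("linear", 0.08)
  cd <- simulateCalibration(c(1, 3), 3000, cv, family = "poisson", seed = 5)
  fit <- fitCalibration(cd, "poisson", "linear")
  cn <- cellCounts(cd)
  A <- sum(rowSums(cn) * doses(cd))
  T <- sum(cn %*% (seq_len(ncol(cn)) - 1))
  # the fitted MLE is sum(y)/A, and the gamma mean prior has shape T
  expect_equal(unname(coef(fit)[1]), T / A, tolerance = 1e-8)
  s <- 21; m <- 120
  lc <- linearCalibrative(s, m, A, T)
  est <- doseEstimate(fit, TestSample(c(m - s, s)), meanPrior = "gamma",
                      gridSize = 4001)
  sm <- doseSummary(est)
  expect_equal(sm$mode, lc$mode, tolerance = 1e-3)
  expect_equal(sm$mean, lc$mean, tolerance = 1e-3)
  expect_equal(sm$sd, lc$sd, tolerance = 1e-3)
  expect_equal(sm$ci, lc$ci, tolerance = 2e-3)
  # analytic density integrates to one
  xg <- seq(0, 60, length.out = 20001)
  expect_equal(pracma::trapz(xg, lc$density(xg)), 1, tolerance = 1e-5)
  # no aberrations pulls the dose to zero with a decreasing density
  lc0 <- linearCalibrative(0, m, A, T)
  expect_equal(lc0$mode, 0)
  xs <- seq(0.01, 2, length.out = 50)
  expect_true(all(diff(lc0$density(xs)) < 0))
})

test_that("degenerate limits: no parameter uncertainty collapses the
           predictive onto the summed response law", {
  # v -> 0, Poisson: q_s is the plain Poisson pmf at m f(x)
  fit0 <- importFit("linquad0", beta = c(3e-3, 2.5e-2),
                    cov = matrix(0, 2, 2))
  x <- 1.4; m <- 200; s <- 9
  f <- curveMean(doseResponse(fit0), x)
  expect_equal(predictiveProb(fit0, s, m, x, "normal"), dpois(s, m * f))
  expect_equal(predictiveProb(fit0, s, m, x, "gamma"), dpois(s, m * f))
  # v -> 0, compound family: the summed-family pmf at (m f, delta)
  fitC <- importFit("linquad0", beta = c(3e-3, 2.5e-2),
                    cov = matrix(0, 3, 3), family = "neymanA", delta = 1.4)
  expect_equal(predictiveProb(fitC, s, m, x, "gamma"),
               countPmf(CountModel("neymanA", m * f, 1.4), s),
               tolerance = 1e-12)
  # delta -> 1: the simplified compound predictive reduces to the
  # Poisson-model predictive at the same (f, v)
  S <- matrix(c(4e-6, -2e-6, -2e-6, 2e-6), 2)
  fitP <- importFit("linquad0", beta = c(3e-3, 2.5e-2), cov = S)
  fitN <- importFit("linquad0", beta = c(3e-3, 2.5e-2),
                    cov = rbind(cbind(S, 0), c(0, 0, 1e-12)),
                    family = "negbin", delta = 1 + 1e-9)
  expect_equal(predictiveProb(fitN, s, m, x, "gamma"),
               predictiveProb(fitP, s, m, x, "gamma"), tolerance = 1e-4)
})

test_that("normal and gamma mean priors agree in total variation below the
           validity bound", {
  fit <- dicFitML()
  ts <- TestSample(cellCounts(exampleCalibration("dicentrics"))[4, ])
  eN <- doseEstimate(fit, ts, meanPrior = "normal")
  eG <- doseEstimate(fit, ts, meanPrior = "gamma",
                     gridMax = max(doses(eN)))
  dG <- approx(doses(eG), densityValues(eG), doses(eN))$y
  tv <- 0.5 * pracma::trapz(doses(eN), abs(densityValues(eN) - dG))
  expect_lt(tv, 0.01)
})

test_that("dose priors act as expected: truncation, flatness, levels", {
  fit <- dicFitML()
  ts <- TestSample(cellCounts(exampleCalibration("dicentrics"))[4, ])
  # uniform(0, 1.3) truncates the support at 1.3
  eU <- doseEstimate(fit, ts, prior = dosePrior("uniform", 0, 1.3),
                     meanPrior = "gamma")
  expect_lte(max(doses(eU)), 1.3)
  expect_gt(tail(densityValues(eU), 1), 0)
  # improper flat vs a wide proper uniform: identical summaries
  eF <- doseEstimate(fit, ts, meanPrior = "gamma", gridMax = 4)
  eW <- doseEstimate(fit, ts, prior = dosePrior("uniform", 0, 4),
                     meanPrior = "gamma")
  expect_equal(unlist(doseSummary(eF)), unlist(doseSummary(eW)),
               tolerance = 1e-6)
  # interval level is honoured
  s90 <- doseSummary(eF, level = 0.90)
  s95 <- doseSummary(eF, level = 0.95)
  expect_gt(s90$ci[1], s95$ci[1])
  expect_lt(s90$ci[2], s95$ci[2])
})

test_that("complete model: point-mass prior reduces to the plug-in
           likelihood and quadrature self-converges", {
  ## nearly degenerate covariance: the 2-D integral collapses onto
  ## L(y | f(x), delta)
  S <- diag(c(1e-16, 1e-16, 1e-16, 1e-14))
  fit <- importFit("linquad", beta = c(3.6e-2, 1.16e-1, 3.2e-2), cov = S,
                   family = "negbin", delta = 1.23, doseRange = c(0, 4))
  ts <- TestSample(c(470, 25, 5))
  x <- 0.4
  lq <- predictiveProbComplete(fit, ts, x, log = TRUE)
  f <- curveMean(doseResponse(fit), x)
  ref <- countLogLik(CountModel("negbin", f, 1.23), ts@freq)
  expect_equal(lq, ref, tolerance = 1e-3)
  ## self-convergence in the number of nodes
  fit2 <- importedMnFit()
  ts2 <- TestSample(cellCounts(exampleCalibration("micronuclei"))[2, ])
  xs <- c(0.08, 0.15)
  a <- predictiveProbComplete(fit2, ts2, xs, nodes = 32, log = TRUE)
  b <- predictiveProbComplete(fit2, ts2, xs, nodes = 64, log = TRUE)
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("95% intervals cover the true dose at the nominal rate on
           simulated patients", {
  fit <- dicFitML()
  hit <- 0
  reps <- 50
  for (r in seq_len(reps)) {
    ts <- simulatePatient(fit, dose = 1.5, m = 500, seed = 400 + r)
    sm <- doseSummary(doseEstimate(fit, ts, meanPrior = "gamma"))
    hit <- hit + (sm$ci[1] <= 1.5 && 1.5 <= sm$ci[2])
  }
  # binomial(50, 0.95): P(X < 42) < 0.001
  expect_gte(hit, 42)
})
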