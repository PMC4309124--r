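test_that("pmf recursions match brute-force compound oracles", {
  kmax <- 30
  for (mu in c(0.3, 1, 4)) {
    for (delta in c(1.2, 1.5, 1.9)) {
      herm <- countPmf(CountModel("hermite", mu, delta), 0:kmax)
      expect_equal(herm, bruteHermite(mu, delta, kmax), tolerance = 1e-10)
      na <- countPmf(CountModel("neymanA", mu, delta), 0:kmax)
      expect_equal(na, bruteNeymanA(mu, delta, kmax), tolerance = 1e-10)
    }
    for (delta in c(1.3, 2.5)) {
      nb <- countPmf(CountModel("negbin", mu, delta), 0:kmax)
      expect_equal(nb, dnbinom(0:kmax, size = mu / (delta - 1),
                               prob = 1 / delta), tolerance = 1e-12)
    }
  }
  # the seed of the Hermite recursion: P(0) = exp(-a-b)
  expect_equal(countPmf(CountModel("hermite", 1, 1.5), 0), exp(-0.75))
})

test_that("pmf normalizes and reproduces the (mu, mu*delta) moments", {
  cases <- list(c("hermite", 2, 1.7), c("neymanA", 1.5, 2.5),
                c("negbin", 2, 2), c("poisson", 3, 1))
  for (cs in cases) {
    md <- CountModel(cs[1], as.numeric(cs[2]), as.numeric(cs[3]))
    k <- 0:300
    p <- countPmf(md, k)
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_equal(sum(k * p), md@mu, tolerance = 1e-8)
    expect_equal(sum(k^2 * p) - sum(k * p)^2, md@mu * md@delta,
                 tolerance = 1e-8)
  }
})

test_that("delta = 1 degenerates every family to Poisson", {
  k <- 0:20
  ref <- dpois(k, 1.3)
  for (fam in c("hermite", "neymanA", "negbin")) {
    near <- countPmf(CountModel(fam, 1.3, 1 + 1e-9), k)
    expect_equal(near, ref, tolerance = 1e-6)
  }
  # delta exactly 1 dispatches to the Poisson family
  expect_identical(CountModel("negbin", 1.3, 1)@family, "poisson")
})

test_that("invalid parameters and counts are rejected", {
  expect_error(CountModel("hermite", 1, 2.3), "delta <= 2")
  expect_error(CountModel("poisson", 1, 1.4), "delta = 1")
  expect_error(CountModel("negbin", -1, 1.5), "positive")
  expect_error(CountModel("negbin", 1, 0.8), ">= 1")
  expect_error(countPmf(CountModel("poisson", 1), -1), "nonnegative")
})

test_that("log-likelihood equals the per-cell product and is maximized at
           the sample mean for Poisson", {
  # hand computation: two cells with 0, one with 1, Poisson mean 1
  expect_equal(countLogLik(CountModel("poisson", 1), c(2, 1)), -3)
  # brute per-cell product on a pooled frequency row
  freq <- c(4773, 206, 19, 2)
  md <- CountModel("negbin", 0.05, 1.23)
  cells <- rep(0:3, freq)
  expect_equal(countLogLik(md, freq),
               sum(log(countPmf(md, cells))), tolerance = 1e-10)
  # sample mean is the Poisson MLE
  ybar <- sum((0:3) * freq) / sum(freq)
  llAt <- function(mu) countLogLik(CountModel("poisson", mu), freq)
  expect_gt(llAt(ybar), llAt(ybar * 1.05))
  expect_gt(llAt(ybar), llAt(ybar * 0.95))
  # flagged, not silently -Inf
  expect_error(countLogLik(CountModel("poisson", 1e-20), c(0, 5)),
               "zero probability")
})

test_that("samplers reproduce the requested mean and dispersion", {
  set.seed(42)
  f1 <- countSample(CountModel("poisson", 0.056), 1e5)
  k <- seq_along(f1) - 1
  ybar <- sum(k * f1) / sum(f1)
  expect_lt(abs(ybar - 0.056), 3 * sqrt(0.056 / 1e5))

  f2 <- countSample(CountModel("hermite", 1, 1.5), 1e5)
  st <- uTest(f2)
  # dispersion index of a Hermite sample concentrates on delta
  expect_lt(abs(st$d - 1.5), 3 * 0.01)  # MC sd of d is ~2.4/sqrt(n) here

  # overdispersed NB sampling is flagged by the u-test
  f3 <- countSample(CountModel("negbin", 0.05, 1.231), 5000)
  expect_gt(uTest(f3)$u, 2)

  expect_error(countSample(CountModel("poisson", 1), 0), ">= 1")
})

test_that("Hermite recursion stays normalized at large mu (rescaled
           linear-space recursion)", {
  md <- CountModel("hermite", 500, 1.5)
  k <- 0:1200
  lp <- countPmf(md, k, log = TRUE)
  expect_lt(abs(sum(exp(lp)) - 1), 1e-8)
  expect_equal(sum(k * exp(lp)), 500, tolerance = 1e-8)
  # log P(0) = -(a + b) is far below double underflow yet finite
  expect_equal(lp[1], -(500 * 0.5 + 500 * 0.25))
})
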