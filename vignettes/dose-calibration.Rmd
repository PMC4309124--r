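---
title: "Count-data inverse regression for cytogenetic dose estimation"
author: "doseCalib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Count-data inverse regression for cytogenetic dose estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doseCalib)
```

## The problem

After an accidental or therapeutic radiation exposure, the absorbed dose
can be estimated biologically: ionizing radiation induces chromosome
aberrations (dicentrics, micronuclei) in peripheral blood lymphocytes, and
the mean number of aberrations per cell grows with dose in a reproducible
way. A laboratory first builds a *calibration curve* by irradiating blood
*in vitro* at known doses $x_i$ and scoring $n_i$ cells per dose; the count
$y_{ij}$ in each cell is modelled as a draw from a count distribution with
mean $f(x_i, \beta)$. Given a patient sample of $m$ scored cells
$\tilde y_1, \dots, \tilde y_m$, the task is *inverse* regression: infer
the unknown dose $x$ from the counts.

`doseCalib` implements a Bayesian-type solution in which the calibration
stage stays frequentist (as biodosimetry practice prescribes) and its
uncertainty is carried into the dose estimate through a delta-method
*mean prior*. The output is a normalized *calibrative density*
$f(x \mid \tilde y) \propto p(x)\, q_s(x)$ over dose, where $p(x)$ is a
prior for the dose and $q_s(x)$ the predictive probability of the observed
aberration total $s = \sum_i \tilde y_i$ at candidate dose $x$.

## Response families

Low-LET acute exposures give equidispersed (Poisson) counts; high-LET or
protracted exposures are typically overdispersed. The package supports the
Poisson law and three two-parameter compound Poisson laws, all
parametrized by the population mean $\mu$ and dispersion index
$\delta = \sigma^2/\mu$:

| family | compound representation | $\delta$ range |
|---|---|---|
| Poisson | — | $\delta = 1$ |
| Neyman A | $\mathrm{Pois}(\mu/(\delta-1)) \vee \mathrm{Pois}(\delta-1)$ | $\delta > 1$ |
| negative binomial | $\mathrm{Pois}(\mu \log\delta/(\delta-1)) \vee \mathrm{Log}((\delta-1)/\delta)$ | $\delta > 1$ |
| Hermite | $\mathrm{Pois}(\mu/(2(\delta-1))) \vee \mathrm{Bin}(2, \delta-1)$ | $1 < \delta \le 2$ |

Here $N \vee \xi$ denotes a Poisson-stopped sum $\sum_{i=1}^N \xi_i$: the
physical picture is particles traversing the nucleus as a Poisson process,
each producing a random number of aberrations with law $\xi$ (the
*generalizing distribution*). The Hermite family needs $\delta \le 2$
because its generalizing probability is $\delta - 1$. At $\delta = 1$ all
three compound families degenerate to the Poisson, and the package
dispatches them there explicitly. These laws are closed under addition
with common $\delta$, which is what later lets the whole test sample be
summarized by its total $s$.

`CountModel()` exposes the pmf (`countPmf`), frequency-vector
log-likelihood (`countLogLik`) and a compound-representation sampler
(`countSample`). The Hermite pmf uses the two-term recursion
$(r+1)q_{r+1} = a\,q_r + 2b\,q_{r-1}$ with $a = \mu(2-\delta)$,
$b = \mu(\delta-1)/2$, seeded at $q_0 = e^{-a-b}$; the Neyman A pmf runs
the Panjer recursion with Poisson counting and Poisson generalizing law,
so that a single audited code path serves both the pmfs and the compound
predictive distributions below.

## Choosing a family: the u-test

The normalized dispersion statistic of a frequency vector with $n$ cells,
$z$ events, sample mean $\bar y$ and sample variance $s_y^2$
(denominator $n-1$; this convention reproduces the published tables that
ship with the package) is
$$u = (d - 1)\sqrt{\frac{n-1}{2\,(1 - 1/z)}}, \qquad d = s_y^2/\bar y .$$
Under Poisson sampling $u$ is approximately standard normal, and $|u| > 2$
flags over/under-dispersion. `uTest()` reports $\bar y$, $d$, $u$ and the
verdict. Formal model choice is by BIC across the four families
(`bicTable()`), with the convention
$\mathrm{BIC} = -2\ell + p \log N$, $N$ = *total scored cells* — the
natural reading of the per-cell likelihood, and the one that matches the
published model-comparison tables for both bundled datasets.

## Calibration fitting

`fitCalibration()` maximizes
$L(D \mid \Theta) = \prod_{i,j} p(y_{ij} \mid f(x_i, \beta), \delta)$
over the nonnegative coefficients of a linear ($\beta_1 x$),
linear-quadratic ($\beta_2 x^2 + \beta_1 x$) or intercepted
linear-quadratic ($G\beta_2 x^2 + \beta_1 x + \beta_0$, with the
Lea-Catcheside protraction factor $G$ on the quadratic term) curve, plus a
common $\delta$ for compound families. Nonnegativity matters: yields are
frequencies, and the likelihood surface often pushes a coefficient toward
zero at low dose.

Numerical choices:

* **Optimizer.** Moment-based starts (cell-weighted least squares on the
  per-dose means; $\delta$ started at the pooled dispersion coefficient),
  a small multi-start battery, box-constrained L-BFGS-B, then Newton
  polishing on finite-difference derivatives until the relative step falls
  below $10^{-10}$. The published coefficients of both bundled examples
  are reproduced to their printed precision.
* **Covariance.** Inverse of the observed information, evaluated by
  central finite differences of the log-likelihood at the optimum. The
  default relative step is $10^{-4}$: with coefficients of order
  $10^{-3}$–$10^{-2}$ and log-likelihoods of order $10^{3}$–$10^{4}$, a
  $10^{-4}$ relative step balances the $O(h^2)$ truncation error against
  cancellation noise ($\sim \epsilon |\ell| / h^2$), keeping both several
  orders below the parameter variances; it is configurable via
  `hessianStep`. For the Poisson family the finite-difference result is
  tested against the analytic observed information
  $\sum_i z_i f_i^{-2} \nabla f_i \nabla f_i^{t}$.
* **Boundaries.** A fit with some $\hat\beta_j = 0$ or $\hat\delta \to 1$
  is returned with a warning and the parameter kept in the covariance
  (one-sided differences are used at the boundary); refitting a reduced
  model is left to the user.

`importFit()` covers the common situation where only published fit results
are available: it assembles the covariance from standard errors and the
$\beta_1$–$\beta_2$ correlation (a re-estimated background intercept is
taken uncorrelated with the curve coefficients), or accepts a full matrix.

## The mean prior and its validity

The delta method turns the fit uncertainty into a distribution for the
yield at candidate dose $x$:
$\mu \mid x \sim N\!\big(f(x,\hat\beta),\, v(x,\hat\beta)\big)$ with
$v = \nabla f \cdot \hat\Sigma \cdot \nabla f^{t}$, and for compound
families a bivariate normal for $(\mu, \delta) \mid x$ with the trailing
gradient row $(0, \dots, 0, 1)$. Because a normal puts mass on negative
yields, a moment-matched gamma (shape $f^2/v$, rate $f/v$) is the fallback;
the two are practically indistinguishable whenever the shape is large
(`minGammaShape()`).

Mixing the (compound) Poisson test likelihood over the *normal* mean prior
yields a (compound) Hermite predictive, which exists only while the
implied counting dispersion stays $\le 2$. `normalValidityBound()` returns
the largest admissible dose by root bracketing of the family-specific
inequality — $f \ge m v$ (Poisson), $f(\delta-1) \ge m v$ (Neyman A),
$f(\delta-1) \ge m v \log\delta$ (NB), $2f(\delta-1) \ge m v$ (Hermite) —
over $[0, 3 \times$ the calibration maximum$]$ with $10^{-6}$ Gy
tolerance. Beyond the bound the package refuses the normal variant and
directs to the gamma one.

For `minGammaShape()` the relevant dose interval is genuinely a modelling
choice: for a no-intercept curve $f^2/v \to \beta_1^2/\Sigma_{11}$ (small)
as $x \to 0$, so a minimum "over all doses" is dominated by doses the test
sample has already excluded. The package therefore asks for an explicit
range, and the recommended (and test-exercised) choice is the window where
the sample's calibrative density lives — mode $\pm 4$ posterior sd,
rounded outward to the 0.1 Gy resolution of a plotted dose axis and
truncated to $[0,$ validity bound$]$. With intercepted curves this window
reaches 0 and the minimum is $\beta_0^2/\Sigma_{00}$.

## The predictive probability $q_s(x)$

**Poisson responses** admit a closed form. The total $s$ is sufficient,
and mixing $\mathrm{Pois}(m\mu)$ over the mean prior gives

* normal prior: a Hermite pmf with mean $m f$ and variance
  $m f + m^2 v$ (the formal Poisson-normal mixture);
* gamma prior: a negative binomial pmf with the same two moments.

**Compound responses** are handled two ways:

* *Simplified model*: plug in $\hat\delta$; the test total then follows a
  compound Hermite (normal prior) or compound NB (gamma prior)
  distribution whose counting law is $F(c f,\, 1 + c v/f)$ with the
  family-specific scale $c = m/(\delta-1)$, $m\log\delta/(\delta-1)$,
  $m/(2(\delta-1))$ for Neyman A, NB, Hermite, and whose generalizing law
  is the family's own (Poisson, logarithmic, binomial). The compound NB
  probabilities come from the Panjer $(a,b,0)$ recursion
  $q_i = (1 - a f_0)^{-1} \sum_{j=1}^{i} (a + b j/i) f_j\, q_{i-j}$, seeded
  at the counting pgf evaluated at $f_0$ (the seed is written as a pgf
  because it is exact and family-independent; for the logarithmic
  generalizing law $f_0 = 0$ and the prefactor disappears). The compound
  Hermite probabilities come from the dedicated recursion
  $$q_n = \frac{\mu_h}{n} \sum_{i=0}^{n-1} (n-i)\, q_i
  \Big[(2-\delta_h) f_{n-i} + \tfrac{\delta_h - 1}{2}\, r_{n-i}\Big],
  \qquad r_j = \sum_i f_i f_{j-i},$$
  seeded at the Hermite pgf at $f_0$. Both recursions are validated in the
  test suite against brute-force enumeration of the stopped sum and
  against direct quadrature of the mixing integral.
* *Complete model* (`predictiveProbComplete()`, `method = "complete"`):
  no plug-in; the full per-cell likelihood is integrated against the
  bivariate normal prior of $(\mu, \delta)$ by tensor Gauss-Legendre
  quadrature (48 nodes per axis by default) over a $\pm 6$-sd box, with
  $\delta$ truncated to its family range and the computation done in log
  space. Doubling the node count changes the result by less than
  $10^{-6}$ relative in the shipped tests.

**Numerical stability.** All recursions run in linear space — every term
is nonnegative — while tracking a common log-scale offset and rescaling
the history whenever a value overflows a $10^{280}$ threshold. This keeps
$q_s$ computable where $\log q_0$ is of order $-10^{3}$–$-10^{4}$ (e.g.
$m f \approx 5000$ aberrations expected), far below what direct
floating-point evaluation could represent. Doses where the predictive is
*so* small that it underflows even relative to the running scale come back
as zero density, which is the correct rounding for a normalized posterior.

## From $q_s$ to a dose estimate

`doseEstimate()` multiplies $q_s(x)$ by the dose prior — improper flat,
uniform$(a,b)$, or gamma by mean/sd — and normalizes by the trapezoid rule
on a grid. The grid is chosen in two passes: a coarse always-valid
gamma-prior pass locates the posterior support (and, for unbounded priors,
doubles the upper end until the relative edge density drops below
$10^{-10}$, capped at ten times the calibration maximum, then an error);
the final grid has 2001 points (601 for the complete model, whose
integrand is costly, restricted to the expanded support window). When the
normal mean prior is in use the grid is capped at the validity bound, and
an error is raised if the posterior support would be truncated by it.
Residual tail mass at the end of the grid beyond $10^{-4}$ triggers a
warning.

Summaries: the mode is the grid argmax refined by a three-point quadratic;
mean and sd are trapezoid moments; the 95% interval is *equal-tail*,
inverted from the numeric CDF. The equal-tail convention is a deliberate
choice — it reproduces the published example intervals, whereas a
highest-density interval would not be — and a different level can be
requested from `doseSummary()`. Multimodal densities are flagged and the
global mode reported.

For the special case of a linear curve $f = \beta x$ with Poisson
calibration data and a flat dose prior, the whole pipeline collapses to a
closed form (`linearCalibrative()`). Re-deriving it from the gamma mean
prior: the prior at dose $x$ has shape $f^2/v = \beta A$ (independent of
$x$, where $A = \sum n_i x_i$ and $\hat\beta = T/A$ with $T = \sum y_i$
the total calibration aberrations, so the shape is exactly $T$) and rate
$A/x$; mixing gives an NB in $s$, and normalizing over $x$ via the
substitution $u = m x/(A + m x)$ — which maps the posterior to a
$\mathrm{Beta}(s+1,\, T-1)$ law — yields
$$f(x \mid \tilde y) = \frac{m^{s+1} A^{T-1}}{B(s+1,\, T-1)}
\frac{x^s}{(A + m x)^{s+T}},$$
with mode $sA/(mT)$, mean $(A/m)\,B(s+2, T-2)/B(s+1, T-1)$ (requires
$T > 2$) and second moment $(A/m)^2 B(s+3, T-3)/B(s+1, T-1)$ (requires
$T > 3$); when the moments do not exist the density and quantiles are
still returned. The Beta substitution also gives the distribution function
without any special-function machinery, and the test suite cross-validates
the closed form against the generic grid pipeline.

## Synthetic experiments

`simulateCalibration()` and `simulatePatient()` draw cells from the
response families via their compound representations (the Neyman A uses
the fact that a sum of $N$ iid Poissons is Poisson with scaled mean) at
the design doses, with a single top-level seed driving deterministic
per-dose streams. The generator emulates the two bundled experimental
designs — an acute low-LET dicentric experiment (six doses up to 3 Gy,
roughly 1300–2600 cells per dose, Poisson responses) and a protracted
overdispersed micronucleus experiment (eleven doses up to 4 Gy, about
5000 cells per dose, NB responses with $\delta \approx 1.23$) — and is
what the recovery, coverage and $O(1/n)$ tests run on. It does *not*
emulate scorer effects, inter-donor variability, partial-body exposure or
dose-dependent dispersion; passing tests therefore certify the
statistical machinery, not robustness to those real-data features.

Problem sizes in the shipped test suite are chosen to keep a full run
around ten seconds: 40–50 replicates for recovery and coverage
(binomial bands widened accordingly), $10^5$-draw sampler checks, and
1000 replicates for the normality of $u$.

## Known limitations

* Dispersion is a single constant per fit; dose-dependent dispersion
  $\delta = g(x, \gamma)$ is out of scope.
* The complete model is implemented for compound families only (for a
  Poisson fit it coincides with the closed form), and no MCMC or model
  averaging across families is provided.
* The covariance is a plain observed-information inverse; no sandwich or
  profile-likelihood intervals.
* Hermite laws of order above 2, and the Polya-Aeppli and
  Poisson-inverse-Gaussian families, are not implemented.

## A worked run

```{r example, eval = FALSE}
cd <- exampleCalibration("dicentrics")
uTest(cellCounts(cd)[4, ])          # held-out 1.5 Gy sample: u = 0.092
calib <- dropDose(cd, 1.5)
bicTable(calib, "linquad0")         # Poisson preferred
fit <- fitCalibration(calib, "poisson", "linquad0")
ts <- TestSample(cellCounts(cd)[4, ])
doseEstimate(fit, ts, meanPrior = "normal")
```

The resulting density has mode 1.430 Gy, mean 1.432 Gy, sd 0.081 Gy and
95% interval (1.277, 1.593) Gy — recovering the known 1.5 Gy within the
interval, from 1811 cells.
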