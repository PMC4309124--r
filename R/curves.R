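#' Construct a dose-response curve
#'
#' @param form functional form: `"linear"` (\eqn{\beta_1 x}), `"linquad0"`
#'   (\eqn{\beta_2 x^2 + \beta_1 x}) or `"linquad"`
#'   (\eqn{G\beta_2 x^2 + \beta_1 x + \beta_0}).
#' @param beta coefficient vector, ordered `(beta0,) beta1, beta2` as the
#'   form requires; names are attached automatically.
#' @param G Lea-Catcheside dose-protraction factor in `[0, 1]`; multiplies
#'   the quadratic term of the `"linquad"` form (1 = acute exposure).
#' @return a [DoseResponseCurve-class] object.
#' @examples
#' cv <- DoseResponseCurve("linquad0", c(3.1e-3, 2.5e-2))
#' curveMean(cv, c(1, 2))
#' @export
DoseResponseCurve <- function(form = c("linquad0", "linquad", "linear"),
                              beta, G = 1) {
  form <- match.arg(form)
  want <- switch(form, linear = "beta1", linquad0 = c("beta1", "beta2"),
                 linquad = c("beta0", "beta1", "beta2"))
  beta <- as.numeric(beta)
  if (length(beta) != length(want))
    stop(sprintf("form '%s' needs %d coefficient(s): %s", form,
                 length(want), paste(want, collapse = ", ")))
  names(beta) <- want
  new("DoseResponseCurve", form = form, beta = beta, G = G)
}

#' @describeIn DoseResponseCurve mean aberration yield \eqn{f(x, \beta)} at
#'   doses `x`.
#' @param object a `DoseResponseCurve`.
#' @param x numeric vector of doses (Gy).
#' @export
setMethod("curveMean", "DoseResponseCurve", function(object, x) {
  b <- object@beta
  switch(object@form,
    linear = b[["beta1"]] * x,
    linquad0 = b[["beta2"]] * x^2 + b[["beta1"]] * x,
    linquad = object@G * b[["beta2"]] * x^2 + b[["beta1"]] * x +
      b[["beta0"]])
})

#' @describeIn DoseResponseCurve gradient of \eqn{f(x, \beta)} with respect
#'   to the coefficients, one row per dose, columns in coefficient order
#'   (used to propagate the calibration covariance by the delta method).
#' @export
setMethod("curveGradient", "DoseResponseCurve", function(object, x) {
  g <- switch(object@form,
    linear = cbind(x),
    linquad0 = cbind(x, x^2),
    linquad = cbind(rep(1, length(x)), x, object@G * x^2))
  colnames(g) <- names(object@beta)
  g
})

setMethod("show", "DoseResponseCurve", function(object) {
  lab <- switch(object@form,
    linear = "f(x) = beta1*x",
    linquad0 = "f(x) = beta2*x^2 + beta1*x",
    linquad = "f(x) = G*beta2*x^2 + beta1*x + beta0")
  cat("Dose-response curve:", lab, "\n")
  print(signif(object@beta, 5))
  if (object@form == "linquad" && object@G != 1)
    cat("G =", object@G, "\n")
  invisible(object)
})
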