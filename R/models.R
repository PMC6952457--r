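#' @include AllClasses.R
NULL

.checkDose <- function(D, nonneg = TRUE) {
  if (!is.numeric(D) || !length(D) || any(!is.finite(D)))
    stop("doses must be finite numeric values", call. = FALSE)
  if (nonneg && any(D < 0))
    stop("doses must be >= 0", call. = FALSE)
  invisible(D)
}

#' Evaluate the sigmoid specific function
#'
#' The specific function modulates the quadratic dose factor of the
#' intensity-dose model. The default `"generalized"` variant,
#' \deqn{f(D) = f_{min} + \frac{f_{max} - f_{min}}{1 + e^{\alpha (D - D_c)}},}
#' has horizontal asymptotes `fMax` (as D goes to -Inf) and `fMin`
#' (as D goes to +Inf) and is strictly decreasing. The `"literal"` variant,
#' \deqn{f(D) = \frac{(f_{max} - f_{min})\, e^{-\alpha (D - D_c)}}
#'   {1 + e^{-\alpha (D - D_c)}},}
#' has asymptotes `fMax - fMin` and 0 and coincides with the generalized
#' form when `fMin = 0`. See the methods vignette for why the generalized
#' form is the default.
#'
#' @param p a [SpecificFunctionParams-class] object.
#' @param D numeric vector of doses (kGy); any real value is admitted since
#'   the asymptotic behaviour is part of the model.
#' @param variant `"generalized"` (default) or `"literal"`.
#' @return numeric vector of specific-function values, same length as `D`.
#' @examples
#' p <- specificFunctionParams(fMax = 0, fMin = -2, alpha = 0.1, Dc = 30)
#' evalSpecificFunction(p, 30)            # midpoint (fMax + fMin)/2 = -1
#' evalSpecificFunction(p, 30 + 10 * log(3))  # -1.5
#' @export
evalSpecificFunction <- function(p, D,
                                 variant = c("generalized", "literal")) {
  stopifnot(is(p, "SpecificFunctionParams"))
  validObject(p)
  variant <- match.arg(variant)
  if (!is.numeric(D) || any(!is.finite(D)))
    stop("invalid dose: 'D' must be finite numeric", call. = FALSE)
  z <- p@alpha * (D - p@Dc)
  ## logistic evaluated stably for large |z|
  s <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
  if (variant == "generalized")
    p@fMin + (p@fMax - p@fMin) * s
  else
    (p@fMax - p@fMin) * s
}

#' @rdname modelEval
#' @export
setMethod("modelEval", "SpecificFunctionParams",
          function(object, x, ...) evalSpecificFunction(object, x, ...))

#' Evaluate the intensity-dose model
#'
#' `I(D) = iInit + D * (D - D0) * f(D)` where `f` is the sigmoid specific
#' function of the model. Exactly `iInit` at `D = 0` and `D = D0`.
#'
#' @param m an [IntensityDoseModel-class] object.
#' @param D numeric vector of doses in kGy, >= 0.
#' @param variant sigmoid variant, see [evalSpecificFunction()].
#' @return numeric vector of intensities (counts).
#' @export
evalIntensityModel <- function(m, D, variant = "generalized") {
  stopifnot(is(m, "IntensityDoseModel"))
  validObject(m)
  .checkDose(D)
  m@iInit + D * (D - m@D0) * evalSpecificFunction(m@sfp, D, variant)
}

#' @rdname modelEval
#' @export
setMethod("modelEval", "IntensityDoseModel",
          function(object, x, ...) evalIntensityModel(object, x, ...))

#' Evaluate the exponential relaxation model
#'
#' `y(D) = (y0 - yInf) * exp(-D / DC) + yInf`.
#'
#' @param m a [RelaxationModel-class] object.
#' @param D numeric vector of doses in kGy, >= 0.
#' @return numeric vector of property values, bounded between `y0` and
#'   `yInf`.
#' @examples
#' ph <- relaxationModel(y0 = 6.98, yInf = 6.75, DC = 73.4)
#' evalRelaxation(ph, c(0, 73.4, 1e6))
#' @export
evalRelaxation <- function(m, D) {
  stopifnot(is(m, "RelaxationModel"))
  validObject(m)   # DC <= 0 rejected here
  .checkDose(D)
  (m@y0 - m@yInf) * exp(-D / m@DC) + m@yInf
}

#' @rdname modelEval
#' @export
setMethod("modelEval", "RelaxationModel",
          function(object, x, ...) evalRelaxation(object, x))

#' Evaluate an affine link
#'
#' `y = slope * (x - xShift) + intercept`, exactly affine.
#'
#' @param m a [LinearLinkModel-class] object.
#' @param x numeric vector of predictor values (finite).
#' @return numeric vector of response values.
#' @export
evalLinearLink <- function(m, x) {
  stopifnot(is(m, "LinearLinkModel"))
  validObject(m)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("predictor values must be finite numeric", call. = FALSE)
  m@slope * (x - m@xShift) + m@intercept
}

#' @rdname modelEval
#' @export
setMethod("modelEval", "LinearLinkModel",
          function(object, x, ...) evalLinearLink(object, x))

#' Characteristic dose of the sigmoid
#'
#' The reciprocal of the sigmoid steepness, `delta = 1/alpha`, a dose (kGy)
#' characterizing how sharply the specific function switches between its
#' asymptotes.
#'
#' @param p a [SpecificFunctionParams-class] object, or a positive numeric
#'   `alpha` directly.
#' @return the characteristic dose in kGy.
#' @export
characteristicDose <- function(p) {
  alpha <- if (is(p, "SpecificFunctionParams")) p@alpha else as.numeric(p)
  if (!.scalarOk(alpha) || alpha <= 0)
    stop("alpha must be a positive finite scalar", call. = FALSE)
  1 / alpha
}

#' Tangent-intercept construction of the relaxation dose
#'
#' The tangent to the relaxation curve at `D = 0` reaches the high-dose
#' asymptote `yInf` at exactly `D = DC`; this is the graphical construction
#' used to read the characteristic relaxation dose off a plot. The returned
#' value equals `m@DC` analytically.
#'
#' @param m a [RelaxationModel-class] object with `y0 != yInf`.
#' @return the abscissa (kGy) where the initial tangent meets the asymptote.
#' @export
tangentInterceptDose <- function(m) {
  stopifnot(is(m, "RelaxationModel"))
  validObject(m)
  if (m@y0 == m@yInf)
    stop("degenerate model: y0 equals yInf, tangent is horizontal",
         call. = FALSE)
  ## slope at 0 is -(y0 - yInf)/DC; tangent y0 + slope*D hits yInf at D = DC
  slope0 <- -(m@y0 - m@yInf) / m@DC
  (m@yInf - m@y0) / slope0
}
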