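#' @include AllGenerics.R
NULL

.scalarOk <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## ---------------------------------------------------------------- models ----

#' Sigmoid specific-function parameters
#'
#' Parameters of the Fermi-Dirac-type sigmoid factor that modulates the
#' quadratic dose term of the peak-intensity model: upper asymptote `fMax`,
#' lower asymptote `fMin` (intensity per squared dose), steepness `alpha`
#' (1/kGy, > 0) and critical dose `Dc` (kGy) at the inflection point. The
#' reciprocal `1/alpha` is the characteristic dose, see
#' [characteristicDose()].
#'
#' @slot fMax,fMin numeric(1), the two horizontal asymptotes, `fMax > fMin`.
#' @slot alpha numeric(1), steepness in 1/kGy, strictly positive.
#' @slot Dc numeric(1), inflection-point dose in kGy.
#' @seealso [specificFunctionParams()], [evalSpecificFunction()]
#' @export
setClass("SpecificFunctionParams",
  representation(fMax = "numeric", fMin = "numeric",
                 alpha = "numeric", Dc = "numeric"))

setValidity("SpecificFunctionParams", function(object) {
  msg <- character()
  for (s in c("fMax", "fMin", "alpha", "Dc"))
    if (!.scalarOk(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a finite numeric scalar", s))
  if (!length(msg)) {
    if (object@fMax <= object@fMin) msg <- c(msg, "fMax must exceed fMin")
    if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' @param fMax,fMin,alpha,Dc see slots of [SpecificFunctionParams-class].
#' @rdname SpecificFunctionParams-class
#' @export
specificFunctionParams <- function(fMax, fMin, alpha, Dc) {
  new("SpecificFunctionParams", fMax = as.numeric(fMax),
      fMin = as.numeric(fMin), alpha = as.numeric(alpha), Dc = as.numeric(Dc))
}

#' Peak intensity versus dose model
#'
#' Intensity of one diffraction peak as a function of absorbed dose:
#' `I(D) = I(0) + D * (D - D0) * f(D)` with `f` the sigmoid specific
#' function. The quadratic factor vanishes at `D = 0` and at the optimized
#' dose `D = D0`, so the peak intensity returns exactly to its
#' pre-irradiation value there.
#'
#' @slot iInit numeric(1), peak intensity before irradiation (counts, > 0).
#' @slot D0 numeric(1), optimized dose in kGy, > 0.
#' @slot sfp a [SpecificFunctionParams-class] object.
#' @seealso [intensityDoseModel()], [evalIntensityModel()],
#'   [findOptimizedDose()]
#' @export
setClass("IntensityDoseModel",
  representation(iInit = "numeric", D0 = "numeric",
                 sfp = "SpecificFunctionParams"))

setValidity("IntensityDoseModel", function(object) {
  msg <- character()
  if (!.scalarOk(object@iInit) || object@iInit <= 0)
    msg <- c(msg, "iInit must be a positive finite scalar")
  if (!.scalarOk(object@D0) || object@D0 <= 0)
    msg <- c(msg, "D0 must be a positive finite scalar")
  v <- validObject(object@sfp, test = TRUE)
  if (!isTRUE(v)) msg <- c(msg, v)
  if (length(msg)) msg else TRUE
})

#' @param iInit,D0 see slots of [IntensityDoseModel-class].
#' @param sfp a [SpecificFunctionParams-class] object.
#' @rdname IntensityDoseModel-class
#' @export
intensityDoseModel <- function(iInit, D0, sfp) {
  new("IntensityDoseModel", iInit = as.numeric(iInit), D0 = as.numeric(D0),
      sfp = sfp)
}

#' Exponential dose-relaxation model
#'
#' Exponential approach of a property (pH of the aqueous solution, melting
#' point of the solid) from its unirradiated value `y0` to a high-dose
#' asymptote `yInf`: `y(D) = (y0 - yInf) * exp(-D/DC) + yInf`. The
#' characteristic dose `DC` is also the abscissa intercept of the tangent at
#' `D = 0` with the asymptote ([tangentInterceptDose()]).
#'
#' @slot y0 numeric(1), property value before irradiation.
#' @slot yInf numeric(1), asymptotic value at very high dose.
#' @slot DC numeric(1), characteristic relaxation dose in kGy, > 0.
#' @seealso [relaxationModel()], [evalRelaxation()], [fitRelaxation()]
#' @export
setClass("RelaxationModel",
  representation(y0 = "numeric", yInf = "numeric", DC = "numeric"))

setValidity("RelaxationModel", function(object) {
  msg <- character()
  for (s in c("y0", "yInf", "DC"))
    if (!.scalarOk(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a finite numeric scalar", s))
  if (!length(msg) && object@DC <= 0) msg <- c(msg, "DC must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param y0,yInf,DC see slots of [RelaxationModel-class].
#' @rdname RelaxationModel-class
#' @export
relaxationModel <- function(y0, yInf, DC) {
  new("RelaxationModel", y0 = as.numeric(y0), yInf = as.numeric(yInf),
      DC = as.numeric(DC))
}

#' Affine link between two properties
#'
#' Exactly affine model `y = slope * (x - xShift) + intercept` used for the
#' mutual correlations between property pairs (melting point vs pH; UV
#' content deviation vs water content deviation) and for the through-origin
#' relative-intensity proportionality between diffraction peaks.
#'
#' @slot slope numeric(1), in response units per predictor unit.
#' @slot intercept numeric(1), in response units.
#' @slot xShift numeric(1), predictor offset (default 0).
#' @seealso [linearLinkModel()], [evalLinearLink()], [fitLinear()]
#' @export
setClass("LinearLinkModel",
  representation(slope = "numeric", intercept = "numeric", xShift = "numeric"))

setValidity("LinearLinkModel", function(object) {
  msg <- character()
  for (s in c("slope", "intercept", "xShift"))
    if (!.scalarOk(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a finite numeric scalar", s))
  if (length(msg)) msg else TRUE
})

#' @param slope,intercept,xShift see slots of [LinearLinkModel-class].
#' @rdname LinearLinkModel-class
#' @export
linearLinkModel <- function(slope, intercept = 0, xShift = 0) {
  new("LinearLinkModel", slope = as.numeric(slope),
      intercept = as.numeric(intercept), xShift = as.numeric(xShift))
}

## ----------------------------------------------------------- diffraction ----

#' One diffractogram as a table of peaks
#'
#' A peak table holds, for a single absorbed dose, the ordered diffraction
#' peaks as rows of `(symbol, twoSinTheta, recipD, intensity)`. `twoSinTheta`
#' is the dimensionless abscissa 2sin(theta); `recipD` the reciprocal
#' d-spacing in 1/Angstrom. Intensities are optional (`NA` when only
#' positions are known), as is `recipD` for intensity-only ("XY") input.
#'
#' @slot dose numeric(1), absorbed dose in kGy, >= 0.
#' @slot peaks data.frame with columns `symbol`, `twoSinTheta`, `recipD`,
#'   `intensity`; sorted ascending by `twoSinTheta`, unique symbols.
#' @slot source character(1), free-text provenance.
#' @seealso [peakTable()], [readPeakTable()], [fitBraggWavelength()]
#' @export
setClass("PeakTable",
  representation(dose = "numeric", peaks = "data.frame", source = "character"))

setValidity("PeakTable", function(object) {
  msg <- character()
  if (!.scalarOk(object@dose) || object@dose < 0)
    msg <- c(msg, "dose must be a finite scalar >= 0")
  p <- object@peaks
  need <- c("symbol", "twoSinTheta", "recipD", "intensity")
  if (!all(need %in% names(p)))
    return(paste("peaks must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(p$symbol)) msg <- c(msg, "peak symbols must be unique")
  if (is.unsorted(p$twoSinTheta, strictly = FALSE))
    msg <- c(msg, "peaks must be sorted ascending by twoSinTheta")
  if (any(!is.finite(p$twoSinTheta)) ||
      any(p$twoSinTheta <= 0 | p$twoSinTheta >= 2))
    msg <- c(msg, "twoSinTheta must lie in (0, 2)")
  if (any(p$recipD[!is.na(p$recipD)] <= 0))
    msg <- c(msg, "recipD must be > 0 where present")
  if (any(p$intensity[!is.na(p$intensity)] < 0))
    msg <- c(msg, "intensity must be >= 0 where present")
  if (length(msg)) msg else TRUE
})

#' @param dose absorbed dose in kGy.
#' @param symbol character vector of single-letter peak labels.
#' @param twoSinTheta,recipD,intensity numeric peak columns; `recipD` and
#'   `intensity` may contain `NA`.
#' @param source provenance string.
#' @rdname PeakTable-class
#' @export
peakTable <- function(dose, symbol, twoSinTheta, recipD = NA_real_,
                      intensity = NA_real_, source = "") {
  n <- length(twoSinTheta)
  p <- data.frame(symbol = as.character(symbol),
                  twoSinTheta = as.numeric(twoSinTheta),
                  recipD = rep_len(as.numeric(recipD), n),
                  intensity = rep_len(as.numeric(intensity), n),
                  stringsAsFactors = FALSE)
  p <- p[order(p$twoSinTheta), , drop = FALSE]
  rownames(p) <- NULL
  new("PeakTable", dose = as.numeric(dose), peaks = p,
      source = as.character(source))
}

#' Result of a Bragg-law wavelength regression
#'
#' Least-squares line of reciprocal d-spacing against 2sin(theta) for one
#' peak table; by Bragg's law (first order) the slope is 1/lambda.
#'
#' @slot wavelength numeric(1), fitted X-ray wavelength in Angstrom
#'   (reciprocal of the slope).
#' @slot slope,intercept numeric(1), regression coefficients in 1/Angstrom
#'   (intercept fixed at 0 for the through-origin convention).
#' @slot r numeric(1), Pearson correlation of the two columns.
#' @slot nPeaks integer(1), number of peaks used (>= 3).
#' @slot throughOrigin logical(1), regression convention used.
#' @slot dose numeric(1), dose tag carried from the peak table.
#' @seealso [fitBraggWavelength()], [summarizeWavelengths()]
#' @export
setClass("BraggFit",
  representation(wavelength = "numeric", slope = "numeric",
                 intercept = "numeric", r = "numeric", nPeaks = "integer",
                 throughOrigin = "logical", dose = "numeric"))

setValidity("BraggFit", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(object@wavelength, 1 / object@slope)))
    msg <- c(msg, "wavelength must equal 1/slope")
  if (!is.na(object@r) && (object@r < -1 || object@r > 1))
    msg <- c(msg, "r must lie in [-1, 1]")
  if (object@nPeaks < 3L) msg <- c(msg, "nPeaks must be >= 3")
  if (length(msg)) msg else TRUE
})

## --------------------------------------------------------------- fitting ----

#' Regression diagnostics container
#'
#' Estimates and diagnostics common to every regression in the package.
#' `r` is the Pearson correlation between observed and fitted values (for a
#' simple linear fit this is the x-y Pearson correlation). A result with
#' `converged = FALSE` must not feed downstream dose reports without an
#' explicit override.
#'
#' @slot params named numeric, parameter estimates.
#' @slot stderr named numeric, asymptotic standard errors (`NA` when the
#'   design is degenerate).
#' @slot r numeric(1), goodness-of-fit correlation, in `[-1, 1]` or `NA`.
#' @slot residuals numeric, observed minus fitted.
#' @slot converged logical(1).
#' @slot nIter integer(1), iterations used (0 for closed-form fits).
#' @slot units named character, parameter units.
#' @export
setClass("FitResult",
  representation(params = "numeric", stderr = "numeric", r = "numeric",
                 residuals = "numeric", converged = "logical",
                 nIter = "integer", units = "character"))

setValidity("FitResult", function(object) {
  msg <- character()
  if (!is.na(object@r) && (object@r < -1 - 1e-12 || object@r > 1 + 1e-12))
    msg <- c(msg, "r must lie in [-1, 1] or be NA")
  if (is.null(names(object@params)) && length(object@params))
    msg <- c(msg, "params must be named")
  if (length(msg)) msg else TRUE
})

.fitResult <- function(params, stderr, r, residuals, converged, nIter,
                       units = character()) {
  if (!length(stderr)) stderr <- setNames(rep(NA_real_, length(params)),
                                          names(params))
  new("FitResult", params = params, stderr = stderr, r = as.numeric(r),
      residuals = as.numeric(residuals), converged = isTRUE(converged),
      nIter = as.integer(nIter), units = units)
}

## ---------------------------------------------------------- dose series -----

#' A physicochemical property sampled over a dose grid
#'
#' @slot label character(1), property name (e.g. `"pH"`).
#' @slot units character(1), free text.
#' @slot doses numeric, strictly increasing dose grid in kGy, >= 0.
#' @slot values numeric, measurements, same length as `doses`.
#' @seealso [doseSeries()], [readDoseSeries()], [analyze()]
#' @export
setClass("DoseSeries",
  representation(label = "character", units = "character",
                 doses = "numeric", values = "numeric"))

setValidity("DoseSeries", function(object) {
  msg <- character()
  if (length(object@doses) != length(object@values))
    msg <- c(msg, "doses and values must have equal length")
  if (any(!is.finite(object@doses)) || any(!is.finite(object@values)))
    msg <- c(msg, "doses and values must be finite")
  if (length(object@doses) && (any(object@doses < 0) ||
      is.unsorted(object@doses, strictly = TRUE)))
    msg <- c(msg, "doses must be strictly increasing and >= 0")
  if (length(msg)) msg else TRUE
})

#' @param label,units,doses,values see slots of [DoseSeries-class].
#' @rdname DoseSeries-class
#' @export
doseSeries <- function(label, doses, values, units = "") {
  new("DoseSeries", label = as.character(label), units = as.character(units),
      doses = as.numeric(doses), values = as.numeric(values))
}

## ------------------------------------------------------------ simulation ----

#' Configuration of a seeded simulation
#'
#' @slot seed integer(1), RNG seed.
#' @slot doseGrid numeric, ascending dose grid in kGy.
#' @slot noiseSd numeric(1), additive Gaussian noise standard deviation in
#'   property units (interpreted as a relative sd by the intensity
#'   generator, and as a wavelength jitter sd in Angstrom by the
#'   diffractogram generator), >= 0.
#' @slot modelParams the generating model object.
#' @slot replicates integer(1), >= 1.
#' @seealso [simulateRelaxationSeries()], [simulateIntensitySeries()],
#'   [simulateDiffractogram()]
#' @export
setClass("SimulationConfig",
  representation(seed = "integer", doseGrid = "numeric", noiseSd = "numeric",
                 modelParams = "ANY", replicates = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (!.scalarOk(object@noiseSd) || object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be >= 0")
  if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
  if (!length(object@doseGrid) || is.unsorted(object@doseGrid, strictly = TRUE))
    msg <- c(msg, "doseGrid must be non-empty and strictly increasing")
  if (length(msg)) msg else TRUE
})

#' @param seed,doseGrid,noiseSd,modelParams,replicates see slots of
#'   [SimulationConfig-class].
#' @rdname SimulationConfig-class
#' @export
simulationConfig <- function(seed, doseGrid, noiseSd = 0, modelParams = NULL,
                             replicates = 1L) {
  new("SimulationConfig", seed = as.integer(seed),
      doseGrid = as.numeric(doseGrid), noiseSd = as.numeric(noiseSd),
      modelParams = modelParams, replicates = as.integer(replicates))
}

## ---------------------------------------------------------------- report ----

#' Assembled dose-response analysis
#'
#' Container produced by [analyze()]: per-series fitted models with
#' diagnostics, derived doses (optimized dose D0, characteristic doses DC
#' and delta = 1/alpha), discrete extrema, mutual correlations and
#' extrapolation summaries. Derived doses from non-converged fits are
#' flagged provisional.
#'
#' @slot fits named list of `list(model =, fit =)` per series.
#' @slot derived data.frame of derived doses with a `provisional` flag.
#' @slot extrema named list of extrema data.frames per series.
#' @slot correlations named list of mutual-correlation results.
#' @slot extrapolations named list of extrapolation summaries.
#' @slot config list, the configuration the analysis ran under.
#' @export
setClass("AnalysisReport",
  representation(fits = "list", derived = "data.frame", extrema = "list",
                 correlations = "list", extrapolations = "list",
                 config = "list"))

## ------------------------------------------------------------- accessors ----

#' Accessors for radstab classes
#'
#' Small read-only accessors: `dose()` and `peaks()` for
#' [PeakTable-class]; `doses()`, `measurements()`, `seriesLabel()`,
#' `seriesUnits()` for [DoseSeries-class]; `wavelength()` for
#' [BraggFit-class]; `fitParams()`, `fitStderr()`, `goodnessR()`,
#' `converged()`, `iterations()` and `residuals()` for [FitResult-class].
#'
#' @param object the object to access.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("dose", "PeakTable", function(object) object@dose)

#' @rdname accessors
#' @export
setMethod("peaks", "PeakTable", function(object) object@peaks)

#' @rdname accessors
#' @export
setMethod("doses", "DoseSeries", function(object) object@doses)

#' @rdname accessors
#' @export
setMethod("measurements", "DoseSeries", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("seriesLabel", "DoseSeries", function(object) object@label)

#' @rdname accessors
#' @export
setMethod("seriesUnits", "DoseSeries", function(object) object@units)

#' @rdname accessors
#' @export
setMethod("wavelength", "BraggFit", function(object) object@wavelength)

#' @rdname accessors
#' @export
setMethod("dose", "BraggFit", function(object) object@dose)

#' @rdname accessors
#' @export
setMethod("goodnessR", "BraggFit", function(object) object@r)

#' @rdname accessors
#' @export
setMethod("fitParams", "FitResult", function(object) object@params)

#' @rdname accessors
#' @export
setMethod("fitStderr", "FitResult", function(object) object@stderr)

#' @rdname accessors
#' @export
setMethod("goodnessR", "FitResult", function(object) object@r)

#' @rdname accessors
#' @export
setMethod("converged", "FitResult", function(object) object@converged)

#' @rdname accessors
#' @export
setMethod("iterations", "FitResult", function(object) object@nIter)

#' @rdname accessors
#' @importFrom stats residuals
#' @export
setMethod("residuals", "FitResult", function(object, ...) object@residuals)

## ------------------------------------------------------------------ show ----

setMethod("show", "SpecificFunctionParams", function(object) {
  cat(sprintf(
    "SpecificFunctionParams: fMax=%g fMin=%g alpha=%g /kGy (delta=%g kGy) Dc=%g kGy\n",
    object@fMax, object@fMin, object@alpha, 1 / object@alpha, object@Dc))
})

setMethod("show", "IntensityDoseModel", function(object) {
  cat(sprintf("IntensityDoseModel: iInit=%g counts, D0=%g kGy\n",
              object@iInit, object@D0))
  show(object@sfp)
})

setMethod("show", "RelaxationModel", function(object) {
  cat(sprintf("RelaxationModel: y0=%g -> yInf=%g, DC=%g kGy\n",
              object@y0, object@yInf, object@DC))
})

setMethod("show", "LinearLinkModel", function(object) {
  cat(sprintf("LinearLinkModel: y = %g * (x - %g) + %g\n",
              object@slope, object@xShift, object@intercept))
})

setMethod("show", "PeakTable", function(object) {
  cat(sprintf("PeakTable: %d peaks at dose %g kGy%s\n",
              nrow(object@peaks), object@dose,
              if (nzchar(object@source)) paste0(" [", object@source, "]")
              else ""))
  print(utils::head(object@peaks, 4))
  if (nrow(object@peaks) > 4) cat("  ...\n")
})

setMethod("show", "BraggFit", function(object) {
  cat(sprintf(
    "BraggFit (dose %g kGy): lambda=%.5f A, r=%.5f, n=%d peaks%s\n",
    object@dose, object@wavelength, object@r, object@nPeaks,
    if (object@throughOrigin) ", through-origin" else ""))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: r=%s, converged=%s (%d iterations)\n",
              format(object@r, digits = 6), object@converged, object@nIter))
  est <- data.frame(estimate = object@params, stderr = object@stderr)
  print(est)
})

setMethod("show", "DoseSeries", function(object) {
  cat(sprintf("DoseSeries '%s'%s: %d doses, %g-%g kGy\n", object@label,
              if (nzchar(object@units)) paste0(" (", object@units, ")")
              else "", length(object@doses),
              min(object@doses), max(object@doses)))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: seed=%d, %d doses (%g-%g kGy), noiseSd=%g, %d replicate(s)\n",
    object@seed, length(object@doseGrid), min(object@doseGrid),
    max(object@doseGrid), object@noiseSd, object@replicates))
})

setMethod("show", "AnalysisReport", function(object) {
  cat(sprintf(
    "AnalysisReport: %d fitted series, %d extrema scans, %d correlations\n",
    length(object@fits), length(object@extrema), length(object@correlations)))
  if (nrow(object@derived)) print(object@derived)
})
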